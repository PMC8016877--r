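#' Read a FASTQ file into a read table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a plain
#' `data.frame` with one row per read, which is the unit the preprocessing
#' operators work on.
#'
#' @param path Path to a (possibly gzipped) FASTQ file, Phred+33 qualities.
#' @return A `data.frame` with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads `data.frame` with `read_id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  stopifnot(nchar(reads$sequence) == nchar(reads$quality))
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a tRNA reference from FASTA
#'
#' FASTA headers are expected as `ref_id` or `ref_id isoacceptor`; when no
#' isoacceptor token is present the ref_id up to the first underscore is
#' used (the convention written by [write_reference_fasta()]).
#'
#' @param path FASTA file of tRNA sequences.
#' @return A `trna_reference` data.frame (see [make_reference()]).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(x), "[ \t]+")
  ref_id <- vapply(hdr, `[`, character(1), 1L)
  iso <- vapply(hdr, function(h) if (length(h) >= 2) h[2] else NA_character_,
                character(1))
  iso[is.na(iso)] <- sub("_.*$", "", ref_id[is.na(iso)])
  new_trna_reference(ref_id, iso, as.character(x))
}

#' Write a tRNA reference as FASTA
#'
#' @param ref A `trna_reference` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "trna_reference"))
  s <- Biostrings::DNAStringSet(ref$sequence)
  names(s) <- paste(ref$ref_id, ref$isoacceptor)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
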