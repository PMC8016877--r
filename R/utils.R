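DNA_BASES <- c("A", "C", "G", "T")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of plain character strings; U accepted as T.
revcomp <- function(x) {
  x <- toupper(chartr("Uu", "Tt", x))
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(s) paste(rev(s), collapse = ""),
                                character(1)))
}

check_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", toupper(chartr("U", "T", seq)))
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT(U) symbols (first offender: %s)",
                 what, seq[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic child-seed scheme: the master seed plus a stage/library
# counter, folded into 31 bits so adding a library never perturbs the
# streams of earlier ones.
child_seed <- function(master, counter) {
  stopifnot(is.numeric(master), is.numeric(counter), counter >= 0)
  as.integer((as.numeric(master) + 1000003 * as.numeric(counter)) %% 2147483647)
}

# Phred+33 encode/decode for plain quality strings
phred_decode <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_encode <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}

str_to_int <- function(s) utf8ToInt(s)
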