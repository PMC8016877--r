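#' Ungapped alignment of a read against a tRNA reference
#'
#' Slides the read (as-is; sense strand only, small-RNA libraries are
#' stranded and tRFs are sense fragments) across every offset of every
#' reference sequence and scores each placement by its match count.
#' The alignment score is expressed in percent of the read length,
#' `score_percent = 100 * matches / read_length`.  For each reference
#' only the best-scoring offset is kept (ties broken by the smallest
#' start) and hits below `min_score_percent` are dropped.
#'
#' @param read Read sequence as a character scalar, or a list with a
#'   `sequence` element.
#' @param ref A `trna_reference`.
#' @param min_score_percent Minimum reported score (default 85).
#' @return data.frame with columns `ref_id`, `start` (0-based),
#'   `matches`, `score_percent`, one row per reference with a
#'   qualifying hit; zero rows when unmapped.
#' @export
align_read <- function(read, ref, min_score_percent = 85) {
  seq <- if (is.list(read)) read$sequence else read
  stopifnot(inherits(ref, "trna_reference"))
  if (nchar(seq) < 15) stop("read shorter than 15 nt", call. = FALSE)
  r <- utf8ToInt(seq)
  L <- length(r)
  refs_int <- attr(ref, "refs_int") %||% lapply(ref$sequence, utf8ToInt)
  out <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    ri <- refs_int[[i]]
    n_off <- length(ri) - L + 1L
    if (n_off < 1L) next
    # matrix of reference windows vs the read, all offsets at once
    wins <- matrix(ri[outer(0:(n_off - 1L), 1:L, `+`)], n_off, L)
    matches <- rowSums(wins == matrix(r, n_off, L, byrow = TRUE))
    best <- which.max(matches)           # first max = smallest start
    sp <- 100 * matches[best] / L
    if (sp >= min_score_percent) {
      out[[i]] <- data.frame(ref_id = ref$ref_id[i], start = best - 1L,
                             matches = as.integer(matches[best]),
                             score_percent = sp, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(ref_id = character(), start = integer(),
                      matches = integer(), score_percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Precompute integer-coded reference sequences; alignment of a whole
# library reuses them.
index_reference <- function(ref) {
  attr(ref, "refs_int") <- lapply(ref$sequence, utf8ToInt)
  ref
}

#' Classify a read's hits as unmapped, unique or shared
#'
#' No hits gives `unmapped`; hits on exactly one reference give
#' `unique`; otherwise the read is `shared` across every reference
#' whose score is within `best_margin_percent` of the best score
#' (margin 0 keeps only exact ties with the best).
#'
#' @param hits data.frame from [align_read()] (all rows one read).
#' @param best_margin_percent Score margin, in percentage points.
#' @param read_id Optional read id recorded in the assignment.
#' @return A `read_assignment` list: `read_id`, `status`
#'   (`"unmapped"`, `"unique"`, `"shared"`), `refs` (character),
#'   `scores` (numeric, parallel to `refs`).
#' @export
classify <- function(hits, best_margin_percent = 0, read_id = NA_character_) {
  if (!is.null(hits$read_id) && length(unique(hits$read_id)) > 1)
    stop("hits belong to more than one read", call. = FALSE)
  if (nrow(hits) == 0) {
    return(structure(list(read_id = read_id, status = "unmapped",
                          refs = character(), scores = numeric()),
                     class = "read_assignment"))
  }
  best <- max(hits$score_percent)
  keep <- hits$score_percent >= best - best_margin_percent
  hits <- hits[keep, , drop = FALSE]
  status <- if (nrow(hits) == 1) "unique" else "shared"
  structure(list(read_id = read_id, status = status,
                 refs = hits$ref_id, scores = hits$score_percent),
            class = "read_assignment")
}

#' Weighted read counts per reference for one sample
#'
#' Implements the weighted-read apportionment of multi-mapping small-RNA
#' reads: `weighted reads = unique reads + alignment score % * shared
#' reads`.  Two readings of the score term are provided:
#' \describe{
#'   \item{`literal`}{each shared read adds `score_percent/100` to every
#'     reference in its shared set (the formula applied verbatim; a
#'     shared read can contribute total mass below or above 1).}
#'   \item{`normalized`}{each shared read's contributions are its scores
#'     normalized over the shared set, so every mapped read contributes
#'     total mass exactly 1 and weighted counts are conserved.}
#' }
#'
#' @param assignments List of `read_assignment` objects (one sample).
#' @param mode `"literal"` or `"normalized"`.
#' @param ref Optional `trna_reference`; when given, references with no
#'   reads appear as zero rows and isoacceptor labels are attached.
#' @return A `trf_count_table` data.frame with columns `ref_id`,
#'   (`isoacceptor`,) `unique_count`, `shared_contrib`, `weighted`, and
#'   attributes `totals` (`n_mapped`, `n_unique`, `n_shared`) and
#'   `mode`.
#' @export
weighted_counts <- function(assignments, mode = c("literal", "normalized"),
                            ref = NULL) {
  mode <- match.arg(mode)
  status <- vapply(assignments, `[[`, character(1), "status")
  uniq <- unlist(lapply(assignments[status == "unique"], `[[`, "refs"))
  unique_tab <- table(uniq)

  shared_contrib <- numeric()
  for (a in assignments[status == "shared"]) {
    contrib <- if (mode == "literal") a$scores / 100
               else a$scores / sum(a$scores)
    for (j in seq_along(a$refs)) {
      r <- a$refs[j]
      shared_contrib[r] <- (if (r %in% names(shared_contrib))
        shared_contrib[[r]] else 0) + contrib[j]
    }
  }

  ref_ids <- if (!is.null(ref)) ref$ref_id else
    sort(union(names(unique_tab), names(shared_contrib)))
  u <- as.numeric(unique_tab[match(ref_ids, names(unique_tab))])
  u[is.na(u)] <- 0
  s <- as.numeric(shared_contrib[match(ref_ids, names(shared_contrib))])
  s[is.na(s)] <- 0
  out <- data.frame(ref_id = ref_ids, unique_count = as.integer(u),
                    shared_contrib = s, weighted = u + s,
                    stringsAsFactors = FALSE)
  if (!is.null(ref))
    out$isoacceptor <- ref$isoacceptor[match(out$ref_id, ref$ref_id)]
  attr(out, "totals") <- c(n_mapped = sum(status != "unmapped"),
                           n_unique = sum(status == "unique"),
                           n_shared = sum(status == "shared"))
  attr(out, "mode") <- mode
  class(out) <- c("trf_count_table", "data.frame")
  out
}

#' Combine per-sample count tables into a weighted count matrix
#'
#' @param samples Named list of `trf_count_table` objects (names become
#'   column names).
#' @param collapse `"by_ref"` keeps one row per reference;
#'   `"by_isoacceptor"` sums family members (requires isoacceptor labels
#'   in the tables or a `ref`).
#' @param ref Optional `trna_reference` providing the full species set
#'   and the ref-to-isoacceptor map.
#' @return Numeric matrix, species x samples; absent species are 0.
#' @export
count_matrix <- function(samples, collapse = c("by_ref", "by_isoacceptor"),
                         ref = NULL) {
  collapse <- match.arg(collapse)
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  key_of <- function(tab) {
    if (collapse == "by_ref") return(tab$ref_id)
    iso <- tab$isoacceptor
    if (is.null(iso)) {
      if (is.null(ref)) stop("by_isoacceptor collapse needs isoacceptor ",
                             "labels or a reference", call. = FALSE)
      iso <- ref$isoacceptor[match(tab$ref_id, ref$ref_id)]
      if (anyNA(iso)) stop("count table references absent from `ref`",
                           call. = FALSE)
    }
    iso
  }
  keys <- if (!is.null(ref)) {
    unique(if (collapse == "by_ref") ref$ref_id else ref$isoacceptor)
  } else sort(unique(unlist(lapply(samples, key_of))))
  m <- vapply(samples, function(tab) {
    v <- tapply(tab$weighted, key_of(tab), sum)
    out <- as.numeric(v[match(keys, names(v))])
    out[is.na(out)] <- 0
    out
  }, numeric(length(keys)))
  m <- matrix(m, nrow = length(keys),
              dimnames = list(keys, names(samples)))
  m
}

#' Align and quantify one cleaned library against a reference
#'
#' Convenience wrapper: aligns every read (deduplicating identical
#' sequences), classifies unique/shared status, and accumulates the
#' weighted count table.
#'
#' @param reads Read data.frame (e.g. `preprocess_fastq()$reads`) or a
#'   FASTQ path.
#' @param ref A `trna_reference`.
#' @param mode Weighted-count mode, see [weighted_counts()].
#' @param min_score_percent,best_margin_percent See [align_read()] and
#'   [classify()].
#' @return A `trf_count_table` with an `assignments` attribute (the
#'   per-read `read_assignment` list).
#' @export
quantify_sample <- function(reads, ref, mode = c("literal", "normalized"),
                            min_score_percent = 85,
                            best_margin_percent = 0) {
  mode <- match.arg(mode)
  if (!is.data.frame(reads)) reads <- read_fastq(reads)
  ref <- index_reference(ref)
  uniq <- unique(reads$sequence)
  no_hit <- data.frame(ref_id = character(), start = integer(),
                       matches = integer(), score_percent = numeric(),
                       stringsAsFactors = FALSE)
  hit_list <- lapply(uniq, function(s) {
    if (nchar(s) < 15) no_hit else align_read(s, ref, min_score_percent)
  })
  asn_by_seq <- lapply(hit_list, classify,
                       best_margin_percent = best_margin_percent)
  idx <- match(reads$sequence, uniq)
  assignments <- lapply(seq_len(nrow(reads)), function(i) {
    a <- asn_by_seq[[idx[i]]]
    a$read_id <- reads$read_id[i]
    a
  })
  tab <- weighted_counts(assignments, mode, ref = ref)
  attr(tab, "assignments") <- assignments
  tab
}
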