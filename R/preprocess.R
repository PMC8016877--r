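#' Trim a 3' adapter from one read
#'
#' Removes the longest 3' suffix of the read that matches a prefix of
#' the adapter with at least `min_overlap` bases and a mismatch rate at
#' most `max_mismatch_rate`.  Qualities are trimmed in lockstep; a read
#' without a qualifying adapter match is returned unchanged.  Matching
#' is ungapped (no indel-aware matching).
#'
#' @param read List or one-row data.frame with `read_id`, `sequence`,
#'   `quality`.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum suffix/prefix overlap in bases.
#' @param max_mismatch_rate Maximum fraction of mismatching bases in the
#'   overlap, in `[0, 0.5)`.
#' @return The read with the adapter (and its qualities) removed.
#' @export
trim_adapter <- function(read, adapter, min_overlap = 3,
                         max_mismatch_rate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.5)
    stop("max_mismatch_rate must lie in [0, 0.5)", call. = FALSE)
  cut <- adapter_cut_point(read$sequence, adapter, min_overlap,
                           max_mismatch_rate)
  if (cut <= nchar(read$sequence)) {
    read$sequence <- substr(read$sequence, 1L, cut - 1L)
    read$quality <- substr(read$quality, 1L, cut - 1L)
  }
  read
}

# 1-based position where the adapter starts (earliest position whose
# suffix matches an adapter prefix within the mismatch budget), or
# len+1 when no match.  The earliest start is the longest removable
# suffix.
adapter_cut_point <- function(sequence, adapter, min_overlap,
                              max_mismatch_rate) {
  s <- as.integer(charToRaw(sequence))
  a <- as.integer(charToRaw(adapter))
  len <- length(s); alen <- length(a)
  if (len == 0) return(1L)
  for (start in seq_len(len)) {
    ov <- min(len - start + 1L, alen)
    if (ov < min_overlap) break
    mism <- sum(s[start:(start + ov - 1L)] != a[seq_len(ov)])
    if (mism <= max_mismatch_rate * ov) return(start)
  }
  len + 1L
}

#' Sliding-window quality filter
#'
#' A read passes when every sliding window of `window` bases has mean
#' Phred quality at least `min_mean_q` and the read is at least
#' `min_len` long.  Reads shorter than `window` are judged on a single
#' window spanning the whole read.
#'
#' @param read List with `sequence` and `quality` (Phred+33 string).
#' @param window Window width in bases (>= 1).
#' @param min_mean_q Minimum windowed mean Phred score.
#' @param min_len Minimum read length.
#' @return `TRUE` or `FALSE`.
#' @export
quality_pass <- function(read, window = 4, min_mean_q = 15, min_len = 15) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  q <- as.integer(charToRaw(read$quality)) - 33L
  n <- length(q)
  if (n < min_len) return(FALSE)
  w <- min(window, n)
  cs <- c(0L, cumsum(q))
  means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  all(means >= min_mean_q)
}

#' Size-select reads to the tRF window
#'
#' Retains reads whose length lies in `[min_nt, max_nt]`, both ends
#' inclusive (the 30--45 nt tRF gel window), preserving input order.
#'
#' @param reads data.frame of reads (`read_id`, `sequence`, `quality`).
#' @param min_nt,max_nt Inclusive length bounds.
#' @return The filtered data.frame.
#' @export
size_select <- function(reads, min_nt = 30, max_nt = 45) {
  if (min_nt > max_nt) stop("min_nt must be <= max_nt", call. = FALSE)
  len <- nchar(reads$sequence)
  reads[len >= min_nt & len <= max_nt, , drop = FALSE]
}

#' Preprocess a FASTQ library: trim, quality-filter, size-select
#'
#' Stage order follows small-RNA convention: 3' adapter trimming, then
#' the sliding-window quality filter, then size selection to the tRF
#' window.  Reads are never 5'-trimmed.
#'
#' @param in_path Input FASTQ path (or a read data.frame).
#' @param out_path Optional output FASTQ path for surviving reads.
#' @param adapter Adapter sequence; `""` skips trimming.
#' @param min_overlap,max_mismatch_rate Adapter-matching parameters, see
#'   [trim_adapter()].
#' @param window,min_mean_q,min_len Quality-filter parameters, see
#'   [quality_pass()].
#' @param min_nt,max_nt Size-selection bounds (inclusive).
#' @return A `preprocess_stats` list: `n_input`, `n_adapter_trimmed`,
#'   `n_quality_failed`, `n_size_selected`, `length_histogram` (table of
#'   surviving lengths), and `reads` (the surviving read data.frame).
#' @export
preprocess_fastq <- function(in_path, out_path = NULL,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 3, max_mismatch_rate = 0.1,
                             window = 4, min_mean_q = 15, min_len = 15,
                             min_nt = 30, max_nt = 45) {
  reads <- if (is.data.frame(in_path)) in_path else read_fastq(in_path)
  n_input <- nrow(reads)

  n_trimmed <- 0L
  if (nzchar(adapter) && n_input > 0) {
    # the cut point depends only on the sequence: compute per unique
    # sequence (simulated libraries are highly redundant)
    uniq <- unique(reads$sequence)
    cuts <- vapply(uniq, adapter_cut_point, integer(1), adapter = adapter,
                   min_overlap = min_overlap,
                   max_mismatch_rate = max_mismatch_rate, USE.NAMES = FALSE)
    cut <- cuts[match(reads$sequence, uniq)]
    trimmed <- cut <= nchar(reads$sequence)
    n_trimmed <- sum(trimmed)
    reads$sequence <- substr(reads$sequence, 1L, cut - 1L)
    reads$quality <- substr(reads$quality, 1L, cut - 1L)
  }

  pass <- vapply(reads$quality, function(q)
    quality_pass(list(quality = q), window, min_mean_q, min_len),
    logical(1), USE.NAMES = FALSE)
  n_quality_failed <- sum(!pass)
  reads <- reads[pass, , drop = FALSE]

  reads <- size_select(reads, min_nt, max_nt)
  n_size_selected <- nrow(reads)

  if (!is.null(out_path)) write_fastq(reads, out_path)
  structure(list(n_input = n_input,
                 n_adapter_trimmed = n_trimmed,
                 n_quality_failed = n_quality_failed,
                 n_size_selected = n_size_selected,
                 length_histogram = table(nchar(reads$sequence)),
                 reads = reads),
            class = "preprocess_stats")
}
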