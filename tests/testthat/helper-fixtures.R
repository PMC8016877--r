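# Tiny hand-built fixtures shared across test files.

# Two-family reference with known sequences: family X has two identical
# members (forces multi-mapping), family Y is distinct.
toy_reference <- function() {
  x <- paste(rep(c("ACGT"), 20), collapse = "")            # 80 nt
  y <- paste(rep(c("GGTACCTA"), 10), collapse = "")        # 80 nt
  trfheritance:::new_trna_reference(
    ref_id = c("X_1", "X_2", "Y_1"),
    isoacceptor = c("X", "X", "Y"),
    sequence = c(x, x, y))
}

toy_read <- function(sequence, quality = NULL, read_id = "r1") {
  if (is.null(quality))
    quality <- strrep("I", nchar(sequence))               # Q40
  list(read_id = read_id, sequence = sequence, quality = quality)
}

read_df <- function(sequences, quality = NULL) {
  if (!length(sequences))
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  data.frame(read_id = paste0("r", seq_along(sequences)),
             sequence = sequences,
             quality = if (is.null(quality))
               strrep("I", nchar(sequences)) else quality,
             stringsAsFactors = FALSE)
}

# Brute-force ungapped alignment oracle: best match count over every
# offset of every reference, independent of the package scan.
oracle_align <- function(seq, ref, min_score_percent) {
  L <- nchar(seq)
  rows <- list()
  for (i in seq_len(nrow(ref))) {
    rs <- ref$sequence[i]
    n_off <- nchar(rs) - L + 1
    if (n_off < 1) next
    best_m <- -1; best_start <- NA
    for (off in 0:(n_off - 1)) {
      m <- sum(strsplit(substr(rs, off + 1, off + L), "")[[1]] ==
                 strsplit(seq, "")[[1]])
      if (m > best_m) { best_m <- m; best_start <- off }
    }
    sp <- 100 * best_m / L
    if (sp >= min_score_percent)
      rows[[length(rows) + 1]] <- data.frame(
        ref_id = ref$ref_id[i], start = best_start, matches = best_m,
        score_percent = sp, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
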