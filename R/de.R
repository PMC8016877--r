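#' TPM normalization of a weighted count matrix
#'
#' Scales each library (column) to one million.  With
#' `length_normalize = TRUE` counts are first divided by species length
#' in kilobases (classic TPM); the default `FALSE` gives
#' counts-per-million of the weighted counts, appropriate when all
#' species occupy the same narrow fragment-length window.
#'
#' @param counts Non-negative species x samples matrix.
#' @param lengths Named species lengths in nt (required when
#'   `length_normalize`).
#' @param length_normalize Divide by length before scaling.
#' @return Matrix of the same shape; every non-zero column sums to 1e6.
#'   All-zero columns stay zero, with a warning.
#' @export
tpm_normalize <- function(counts, lengths = NULL, length_normalize = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  rate <- counts
  if (length_normalize) {
    if (is.null(lengths)) stop("lengths required", call. = FALSE)
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
      stop("missing length for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (any(lengths[rownames(counts)] <= 0))
      stop("lengths must be > 0", call. = FALSE)
    rate <- counts / (lengths[rownames(counts)] / 1000)
  }
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero column(s) left as zero: ",
                             paste(colnames(counts)[tot == 0],
                                   collapse = ", "))
  sweep_tot <- ifelse(tot == 0, 1, tot)
  sweep(rate, 2, sweep_tot, `/`) * 1e6
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, order-preserving with the
#' input (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Two-condition differential expression of tRF species
#'
#' Tests each species for a difference between two groups on the
#' log2(TPM + 1) scale.  `welch_log` uses Welch's two-sided t-test;
#' `exact_permutation` uses the exact label-permutation distribution of
#' the mean log2 difference (all `choose(nA+nB, nA)` relabelings, which
#' is feasible at the 3--4 replicates typical of sperm RNA-seq).
#' Multiple testing is corrected by Benjamini-Hochberg; a species is
#' called significant when its q-value (or raw p-value, when
#' `use_raw_p`) is below `alpha`.
#'
#' @param expr TPM matrix (species x samples).
#' @param group Named character vector mapping sample -> group label.
#' @param group_a,group_b The two group labels; fold changes and
#'   directions are B relative to A.
#' @param alpha Significance level (default 0.05).
#' @param method `"welch_log"` or `"exact_permutation"`.
#' @param use_raw_p Apply the alpha cut to raw p-values instead of
#'   q-values.
#' @return A `de_result` data.frame: `species`, `mean_a`, `mean_b`
#'   (TPM), `log2_fold_change`, `p_value`, `q_value`, `significant`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
de_test <- function(expr, group, group_a, group_b, alpha = 0.05,
                    method = c("welch_log", "exact_permutation"),
                    use_raw_p = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr))
  if (is.null(names(group))) {
    stopifnot(length(group) == ncol(expr))
    names(group) <- colnames(expr)
  }
  a_cols <- names(group)[group == group_a]
  b_cols <- names(group)[group == group_b]
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  A <- expr[, a_cols, drop = FALSE]
  B <- expr[, b_cols, drop = FALSE]
  lA <- log2(A + 1); lB <- log2(B + 1)

  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- lA[i, ]; y <- lB[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) return(1)
      if (method == "welch_log") return(0)
    }
    if (method == "welch_log") {
      stats::t.test(y, x, var.equal = FALSE)$p.value
    } else {
      permutation_p(x, y)
    }
  }, numeric(1))

  lfc <- rowMeans(lB) - rowMeans(lA)
  q <- bh_adjust(p)
  sig <- (if (use_raw_p) p else q) < alpha
  direction <- ifelse(!sig, "none", ifelse(lfc > 0, "up", "down"))
  out <- data.frame(species = rownames(expr),
                    mean_a = rowMeans(A), mean_b = rowMeans(B),
                    log2_fold_change = lfc,
                    p_value = p, q_value = q,
                    significant = sig, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(group_a = group_a, group_b = group_b)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "decision_on") <- if (use_raw_p) "p_value" else "q_value"
  class(out) <- c("de_result", "data.frame")
  out
}

# Exact two-sided permutation p-value for the difference of means.
# Enumerates every relabeling when feasible, otherwise Monte-Carlo.
permutation_p <- function(x, y, max_exact = 100000) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(y) - mean(x))
  n_comb <- choose(length(pooled), nx)
  tol <- 1e-12
  if (n_comb <= max_exact) {
    combs <- utils::combn(length(pooled), nx)
    stat <- apply(combs, 2, function(idx)
      abs(mean(pooled[-idx]) - mean(pooled[idx])))
    mean(stat >= obs - tol)
  } else {
    stat <- replicate(10000, {
      idx <- sample.int(length(pooled), nx)
      abs(mean(pooled[-idx]) - mean(pooled[idx]))
    })
    (sum(stat >= obs - tol) + 1) / (length(stat) + 1)
  }
}

#' Cross-generation overlap of differentially expressed species
#'
#' The overlap is the set of species significant in both comparisons
#' with the same direction of change (a species up in one generation
#' and down in the other does not count).
#'
#' @param de_f0,de_f1 `de_result` tables over the same species universe.
#' @return An `overlap_report` list: `overlap` (data.frame `species`,
#'   `direction`), `n_overlap`, `n_up_shared`, `n_down_shared`.
#' @export
overlap_analysis <- function(de_f0, de_f1) {
  if (!setequal(de_f0$species, de_f1$species))
    stop("the two comparisons cover different species universes",
         call. = FALSE)
  f1 <- de_f1[match(de_f0$species, de_f1$species), ]
  both <- de_f0$significant & f1$significant &
    de_f0$direction == f1$direction
  overlap <- data.frame(species = de_f0$species[both],
                        direction = de_f0$direction[both],
                        stringsAsFactors = FALSE)
  structure(list(overlap = overlap,
                 n_overlap = nrow(overlap),
                 n_up_shared = sum(overlap$direction == "up"),
                 n_down_shared = sum(overlap$direction == "down")),
            class = "overlap_report")
}

#' Composition summary: combined fraction of the top-k species
#'
#' Ranks species by their grand mean abundance across group means
#' (deterministic tie-break by species label) and reports the combined
#' fraction of the top `top_k` species per sample and per group.
#'
#' @param expr TPM matrix (species x samples).
#' @param group Named sample -> group map (defaults to one group).
#' @param top_k Number of top species (>= 1, <= number of species).
#' @return List with `top_species`, `per_sample` (named fractions) and
#'   `group_mean` (named fractions per group).
#' @export
composition_summary <- function(expr, group = NULL, top_k = 2) {
  stopifnot(is.matrix(expr))
  if (top_k < 1 || top_k > nrow(expr))
    stop("top_k must lie in [1, number of species]", call. = FALSE)
  if (is.null(group))
    group <- stats::setNames(rep("all", ncol(expr)), colnames(expr))
  frac <- sweep(expr, 2, colSums(expr), `/`)
  groups <- unique(group)
  gmeans <- vapply(groups, function(g)
    rowMeans(frac[, names(group)[group == g], drop = FALSE]),
    numeric(nrow(expr)))
  grand <- rowMeans(matrix(gmeans, nrow = nrow(expr)))
  ord <- order(-grand, rownames(expr))
  top <- rownames(expr)[ord[seq_len(top_k)]]
  per_sample <- colSums(frac[top, , drop = FALSE])
  group_mean <- vapply(groups, function(g)
    mean(per_sample[names(group)[group == g]]), numeric(1))
  list(top_species = top, per_sample = per_sample,
       group_mean = stats::setNames(group_mean, groups))
}

#' Per-species group means for expression scatterplots
#'
#' One row per species with group means on the log10(TPM + 1) scale,
#' the table behind treated-vs-control scatterplots.
#'
#' @param expr TPM matrix.
#' @param group Named sample -> group map.
#' @param group_a,group_b Group labels for the x and y axes.
#' @return data.frame `species`, `mean_a`, `mean_b` (log10(TPM + 1)).
#' @export
scatter_table <- function(expr, group, group_a, group_b) {
  a_cols <- names(group)[group == group_a]
  b_cols <- names(group)[group == group_b]
  if (!length(a_cols) || !length(b_cols))
    stop("group labels not found", call. = FALSE)
  data.frame(species = rownames(expr),
             mean_a = rowMeans(log10(expr[, a_cols, drop = FALSE] + 1)),
             mean_b = rowMeans(log10(expr[, b_cols, drop = FALSE] + 1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
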