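#' Seed-match scan of a 3'UTR
#'
#' Scans a UTR (5'->3') for exact Watson-Crick complements of the tRF
#' seed, defined on tRF positions 2-7 (6mer) and 2-8 (7mer), counted
#' 1-based from the tRF 5' end.  Because pairing is antiparallel, a
#' site is the reverse complement of the seed; an adenine immediately
#' 3' of a 7mer site (the base facing tRF position 1) upgrades it to an
#' 8mer.  Overlapping site types are reported once with the strongest
#' type (8mer > 7mer > 6mer).
#'
#' @param trf_sequence tRF sequence, 5'->3' (>= 8 nt; U allowed).
#' @param utr_sequence UTR sequence, 5'->3'.
#' @return data.frame `site_start` (0-based position of the site's
#'   5'-most base on the UTR), `seed_type` (`"6mer"`, `"7mer"`,
#'   `"8mer"`).
#' @export
seed_sites <- function(trf_sequence, utr_sequence) {
  check_alphabet(trf_sequence, "tRF sequence")
  check_alphabet(utr_sequence, "UTR sequence")
  trf <- toupper(chartr("U", "T", trf_sequence))
  utr <- toupper(chartr("U", "T", utr_sequence))
  if (nchar(trf) < 8) stop("tRF must be at least 8 nt", call. = FALSE)

  s7 <- revcomp(substr(trf, 2, 8))   # 7 nt site
  s6 <- revcomp(substr(trf, 2, 7))   # 6 nt site (suffix of s7)
  find_all <- function(pattern, subject) {
    m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  hits7 <- find_all(s7, utr)
  hits6 <- find_all(s6, utr)

  out <- list()
  for (p in hits7) {
    nxt <- substr(utr, p + 8L, p + 8L)
    out[[length(out) + 1L]] <- data.frame(
      site_start = p, seed_type = if (identical(nxt, "A")) "8mer" else "7mer",
      stringsAsFactors = FALSE)
  }
  # a 6mer site is the last 6 nt of a 7mer site: report only 6mers not
  # explained by a 7mer one base upstream
  for (p in hits6) {
    if (!((p - 1L) %in% hits7))
      out[[length(out) + 1L]] <- data.frame(site_start = p,
                                            seed_type = "6mer",
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_start = integer(), seed_type = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out[order(out$site_start), , drop = FALSE]
}

# Position scores for trf aligned antiparallel to a UTR stretch:
# Watson-Crick pair +5, G:U wobble +1, mismatch -3; positions 2-8 of
# the tRF doubled.  Energies: G:C -3, A:T -2, G:U -1 kcal/mol.
duplex_position_tables <- local({
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  function(trf) {
    n <- nchar(trf)
    tb <- strsplit(trf, "", fixed = TRUE)[[1]]
    weight <- ifelse(seq_len(n) >= 2 & seq_len(n) <= 8, 2, 1)
    list(bases = tb, comp = comp[tb], weight = weight, n = n)
  }
})

# Score/energy of trf against one register of the UTR (utr_stretch has
# the same length as trf, given 5'->3'; trf position i faces the
# stretch base at position n - i + 1).
score_register <- function(tt, stretch_rev) {
  wc <- tt$comp == stretch_rev
  gu <- (tt$bases == "G" & stretch_rev == "T") |
        (tt$bases == "T" & stretch_rev == "G")
  per_pos <- ifelse(wc, 5, ifelse(gu, 1, -3)) * tt$weight
  gc_pair <- wc & (tt$bases == "G" | tt$bases == "C")
  at_pair <- wc & !gc_pair
  energy <- -3 * sum(gc_pair) - 2 * sum(at_pair) - 1 * sum(gu)
  c(score = sum(per_pos), energy = energy)
}

#' Duplex score and energy of a tRF against a UTR window
#'
#' Best ungapped antiparallel pairing of the tRF over every register of
#' the window.  Per-position scoring: Watson-Crick match +5, G:U wobble
#' +1, mismatch -3, with tRF positions 2-8 weighted x2.  The energy of
#' the same register sums simplified pair energies (G:C -3.0, A:T -2.0,
#' G:U -1.0 kcal/mol) over paired (Watson-Crick or wobble) positions.
#' This scorer is an explicit, simplified stand-in for miRanda-style
#' duplex evaluation; its score and energy scales are its own.
#'
#' @param trf_sequence tRF sequence 5'->3'.
#' @param utr_window UTR window 5'->3', length in
#'   `[trf length, trf length + 10]`.
#' @return Named numeric `c(score =, energy =)` of the best-scoring
#'   register (energy reported for that register).
#' @export
duplex_score <- function(trf_sequence, utr_window) {
  trf <- toupper(chartr("U", "T", trf_sequence))
  win <- toupper(chartr("U", "T", utr_window))
  check_alphabet(trf, "tRF sequence"); check_alphabet(win, "UTR window")
  n <- nchar(trf)
  if (nchar(win) < n)
    stop("window shorter than the tRF", call. = FALSE)
  if (nchar(win) > n + 10)
    stop("window longer than tRF length + 10", call. = FALSE)
  best <- c(score = -Inf, energy = 0)
  tt <- duplex_position_tables(trf)
  wb <- strsplit(win, "", fixed = TRUE)[[1]]
  for (off in 0:(nchar(win) - n)) {
    stretch_rev <- rev(wb[(off + 1):(off + n)])
    se <- score_register(tt, stretch_rev)
    if (se["score"] > best["score"]) best <- se
  }
  best
}

# Best register of trf against a whole UTR, subject to joint
# thresholds: returns the best-scoring register among those passing
# BOTH score >= score_min and energy <= energy_max, or NULL.
duplex_scan <- function(trf, utr, score_min, energy_max) {
  n <- nchar(trf)
  if (nchar(utr) < n) return(NULL)
  tt <- duplex_position_tables(trf)
  ub <- strsplit(toupper(chartr("U", "T", utr)), "", fixed = TRUE)[[1]]
  best <- NULL
  for (off in 0:(length(ub) - n)) {
    se <- score_register(tt, rev(ub[(off + 1):(off + n)]))
    if (se["score"] >= score_min && se["energy"] <= energy_max &&
        (is.null(best) || se["score"] > best$se["score"]))
      best <- list(se = se, start = off)
  }
  best
}

#' Predict gene targets of tRFs by dual filtering
#'
#' A gene is retained for a tRF only when it passes both predictors:
#' (a) the seed scan finds at least a 7mer site in its 3'UTR, and
#' (b) some register of the UTR attains duplex score >= `score_min`
#' with duplex energy <= `energy_max` (the dual miRanda-style filter,
#' thresholds exposed as configuration; note the score/energy scales
#' are those of this package's scorer).
#'
#' @param trfs Named character vector of tRF sequences (names are tRF
#'   ids).
#' @param utr_db Named character vector of 3'UTR sequences (names are
#'   gene ids), e.g. `make_annotation_db()$utr`.
#' @param score_min Minimum duplex score (default 150).
#' @param energy_max Maximum duplex energy in kcal/mol (default -20).
#' @return data.frame of target hits: `trf_id`, `gene_id`, `site_start`
#'   (strongest seed site, 0-based), `seed_type`, `duplex_score`,
#'   `duplex_energy`.
#' @export
predict_targets <- function(trfs, utr_db, score_min = 150,
                            energy_max = -20) {
  if (!length(utr_db)) stop("empty UTR database", call. = FALSE)
  if (!is.finite(score_min) || !is.finite(energy_max))
    stop("thresholds must be finite", call. = FALSE)
  stopifnot(!is.null(names(trfs)), !is.null(names(utr_db)))
  rank <- c(`8mer` = 3, `7mer` = 2, `6mer` = 1)
  rows <- list()
  for (t in names(trfs)) {
    for (g in names(utr_db)) {
      sites <- seed_sites(trfs[[t]], utr_db[[g]])
      sites <- sites[sites$seed_type %in% c("7mer", "8mer"), , drop = FALSE]
      if (!nrow(sites)) next
      dup <- duplex_scan(trfs[[t]], utr_db[[g]], score_min, energy_max)
      if (is.null(dup)) next
      best_site <- sites[order(-rank[sites$seed_type],
                               sites$site_start)[1], ]
      rows[[length(rows) + 1L]] <- data.frame(
        trf_id = t, gene_id = g,
        site_start = best_site$site_start,
        seed_type = best_site$seed_type,
        duplex_score = unname(dup$se["score"]),
        duplex_energy = unname(dup$se["energy"]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(trf_id = character(), gene_id = character(),
                      site_start = integer(), seed_type = character(),
                      duplex_score = numeric(), duplex_energy = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Hypergeometric term over-representation
#'
#' One-sided hypergeometric test per term (probability of observing at
#' least the seen number of query genes in the term), BH-corrected
#' across terms, filtered at `fdr_max` and sorted by p-value.
#'
#' @param query_genes Character vector of query gene ids (subset of the
#'   universe).
#' @param annotation data.frame with `gene_id` and `term_id` columns.
#' @param universe Character vector: the gene universe.
#' @param fdr_max Report terms with FDR strictly below this (default
#'   0.25).
#' @return data.frame `term_id`, `k` (query hits in term), `K` (term
#'   size), `n` (query size), `N` (universe size), `p_value`, `fdr` —
#'   only rows passing the FDR filter, sorted by `p_value`.  The
#'   unfiltered table is attached as attribute `full`.
#' @export
enrich <- function(query_genes, annotation, universe, fdr_max = 0.25) {
  query_genes <- unique(query_genes)
  if (length(setdiff(query_genes, universe)))
    stop("query gene(s) outside the universe", call. = FALSE)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- split(unique(ann[c("gene_id", "term_id")])$gene_id,
                 unique(ann[c("gene_id", "term_id")])$term_id)
  if (!length(terms)) stop("no non-empty terms", call. = FALSE)
  N <- length(unique(universe))
  n <- length(query_genes)
  rows <- lapply(names(terms), function(t) {
    K <- length(terms[[t]])
    k <- length(intersect(query_genes, terms[[t]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$p_value)
  tab <- tab[order(tab$p_value, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  out <- tab[tab$fdr < fdr_max, , drop = FALSE]
  attr(out, "full") <- tab
  out
}
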