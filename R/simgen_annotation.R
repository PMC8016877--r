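#' Generate a synthetic 3'UTR database and gene-to-term annotation
#'
#' Stand-in for real 3'UTR and functional-term databases: random UTR
#' sequences for a gene universe, a term-membership table with term
#' sizes drawn from a range, and (optionally) perfect complementary
#' sites for chosen tRFs planted into chosen genes' UTRs so the target
#' predictor has a recoverable ground truth.  Everything here is
#' synthetic, including any planted enrichment.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_terms Number of annotation terms.
#' @param genes_per_term_range Integer pair: each term's size is drawn
#'   uniformly from this range (capped at `n_genes`).
#' @param utr_length UTR length in nt.
#' @param planted_terms Optional named list `term_id -> gene ids`;
#'   these memberships are forced into the annotation (genes must be in
#'   the universe).
#' @param planted_sites Optional named list `gene_id -> tRF sequence`;
#'   the full reverse complement of the tRF is inserted at a random
#'   position of that gene's UTR, guaranteeing a seed match and a
#'   high-scoring duplex.
#' @param seed Integer seed; deterministic output.
#' @return List with `utr` (named character vector of UTR sequences,
#'   writable via Biostrings), `annotation` (data.frame `gene_id`,
#'   `term_id`), `genes` (the universe).
#' @export
make_annotation_db <- function(n_genes, n_terms,
                               genes_per_term_range = c(10, 20),
                               utr_length = 500,
                               planted_terms = NULL,
                               planted_sites = NULL,
                               seed = 1) {
  if (n_genes < 1 || n_terms < 1 || utr_length < 1)
    stop("n_genes, n_terms and utr_length must be positive", call. = FALSE)
  set.seed(child_seed(seed, 0L))
  genes <- sprintf("gene%04d", seq_len(n_genes))

  utr <- vapply(seq_len(n_genes), function(i)
    paste(sample(DNA_BASES, utr_length, replace = TRUE), collapse = ""),
    character(1))
  names(utr) <- genes

  if (!is.null(planted_sites)) {
    missing <- setdiff(names(planted_sites), genes)
    if (length(missing))
      stop("planted gene not in universe: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (g in names(planted_sites)) {
      site <- revcomp(planted_sites[[g]])
      if (nchar(site) > utr_length)
        stop("planted site longer than the UTR", call. = FALSE)
      at <- sample.int(utr_length - nchar(site) + 1L, 1)
      substr(utr[g], at, at + nchar(site) - 1L) <- site
    }
  }

  lo <- min(genes_per_term_range[1], n_genes)
  hi <- min(genes_per_term_range[2], n_genes)
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    size <- if (lo == hi) lo else sample(lo:hi, 1)
    data.frame(gene_id = sample(genes, size), term_id = terms[t],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(planted_terms)) {
    missing <- setdiff(unlist(planted_terms), genes)
    if (length(missing))
      stop("planted gene not in universe: ",
           paste(missing, collapse = ", "), call. = FALSE)
    extra <- do.call(rbind, lapply(names(planted_terms), function(t)
      data.frame(gene_id = planted_terms[[t]], term_id = t,
                 stringsAsFactors = FALSE)))
    ann <- unique(rbind(ann, extra))
  }
  ann <- ann[order(ann$term_id, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(utr = utr, annotation = ann, genes = genes)
}

#' Simulate phenotype tables (insulin-tolerance series and tumor onset)
#'
#' Glucose series follow the insulin-tolerance-test schedule (samples at
#' 0, 3, 6, 9, 12 and 30 minutes post-injection): a baseline, an
#' exponential-recovery dip with the nadir near 12 min, and Gaussian
#' noise.  Tumor-onset times are exponential with a per-group rate,
#' right-censored at the end of the monitoring window (20 weeks).
#'
#' @param groups Character vector of group labels.
#' @param n_per_group Animals per group (>= 1).
#' @param itt Named list per group (or single list recycled) with
#'   elements `baseline` (mg/dL), `dip` (max drop, mg/dL), `sd` (noise
#'   SD, mg/dL).
#' @param surv Named list per group (or single list recycled) with
#'   elements `rate` (events/week) and optional `followup` (weeks,
#'   default 20).
#' @param seed Integer seed.
#' @return List with `glucose` (tidy data.frame: `animal_id`, `group`,
#'   `time_min`, `glucose_mg_dl`) and `survival` (`animal_id`, `group`,
#'   `time_weeks`, `event`).
#' @export
simulate_phenotypes <- function(groups, n_per_group,
                                itt = list(baseline = 150, dip = 60, sd = 8),
                                surv = list(rate = 0.05, followup = 20),
                                seed = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  per_group <- function(p) {
    if (!is.null(p$baseline) || !is.null(p$rate))
      stats::setNames(rep(list(p), length(groups)), groups)
    else p
  }
  itt <- per_group(itt); surv <- per_group(surv)
  times <- c(0, 3, 6, 9, 12, 30)
  set.seed(child_seed(seed, 1L))
  glucose <- do.call(rbind, lapply(groups, function(g) {
    p <- itt[[g]]
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      # dip profile peaks at t = 12 min then recovers by 30 min
      shape <- (times / 12) * exp(1 - times / 12)
      v <- p$baseline - p$dip * shape +
        stats::rnorm(length(times), 0, p$sd)
      data.frame(animal_id = sprintf("%s_%02d", g, i), group = g,
                 time_min = times, glucose_mg_dl = pmax(v, 0),
                 stringsAsFactors = FALSE)
    }))
  }))
  set.seed(child_seed(seed, 2L))
  survival <- do.call(rbind, lapply(groups, function(g) {
    p <- surv[[g]]
    fu <- p$followup %||% 20
    t_ev <- stats::rexp(n_per_group, p$rate)
    data.frame(animal_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
               group = g,
               time_weeks = pmin(t_ev, fu),
               event = as.integer(t_ev <= fu),
               stringsAsFactors = FALSE)
  }))
  rownames(glucose) <- rownames(survival) <- NULL
  list(glucose = glucose, survival = survival)
}
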