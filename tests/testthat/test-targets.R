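test_that("seed_sites finds planted and only planted seed matches", {
  trf <- "TACGATCGATCGGATCCGATTGCAGCATGCAAGCTT"
  # plant the reverse complement of positions 2-8 in a neutral background
  site7 <- trfheritance:::revcomp(substr(trf, 2, 8))
  utr <- paste0(strrep("C", 50), site7, strrep("C", 50))
  sites <- seed_sites(trf, utr)
  expect_equal(sites$site_start, 50)
  expect_equal(sites$seed_type, "7mer")

  # adjacent A upgrades to 8mer
  utr8 <- paste0(strrep("C", 50), site7, "A", strrep("C", 20))
  expect_equal(seed_sites(trf, utr8)$seed_type, "8mer")

  # poly-A UTR vs a tRF without a poly-T seed complement: nothing
  expect_equal(nrow(seed_sites(trf, strrep("A", 100))), 0)

  expect_error(seed_sites("ACGTNNNACGT", "ACGT"), "non-ACGT")
  expect_error(seed_sites("ACGT", strrep("A", 20)), "8 nt")
})

test_that("seed_sites equals a brute-force substring oracle", {
  set.seed(11)
  for (i in 1:10) {
    trf <- random_seq(35)
    utr <- random_seq(500)
    got <- seed_sites(trf, utr)
    s7 <- trfheritance:::revcomp(substr(trf, 2, 8))
    s6 <- trfheritance:::revcomp(substr(trf, 2, 7))
    find <- function(pat) {
      hits <- integer(0)
      for (p in 1:(nchar(utr) - nchar(pat) + 1))
        if (substr(utr, p, p + nchar(pat) - 1) == pat)
          hits <- c(hits, p - 1L)
      hits
    }
    h7 <- find(s7)
    h6 <- setdiff(find(s6), h7 + 1L)
    expect_setequal(got$site_start[got$seed_type %in% c("7mer", "8mer")], h7)
    expect_setequal(got$site_start[got$seed_type == "6mer"], h6)
  }
})

test_that("duplex_score matches its closed form and a register oracle", {
  # perfect 40-nt all-G:C duplex: 40*5 + 7*5 seed doubling = 235,
  # energy 40 * -3 = -120
  trf <- strrep("GC", 20)
  window <- trfheritance:::revcomp(trf)
  se <- duplex_score(trf, window)
  expect_equal(unname(se["score"]), 235)
  expect_equal(unname(se["energy"]), -120)

  # completely non-complementary: no pairing at all
  se <- duplex_score(strrep("A", 20), strrep("A", 25))
  expect_lte(se["score"], 0)
  expect_equal(unname(se["energy"]), 0)

  # wobble-only duplex: G opposite T at every position
  se <- duplex_score(strrep("G", 16), strrep("T", 16))
  expect_equal(unname(se["score"]), 16 + 7)   # +1 each, seed doubled
  expect_equal(unname(se["energy"]), -16)

  expect_error(duplex_score(strrep("A", 20), strrep("A", 10)), "shorter")
  expect_error(duplex_score(strrep("A", 20), strrep("A", 35)), "longer")

  # exhaustive register oracle on random pairs
  set.seed(5)
  for (i in 1:10) {
    trf <- random_seq(20)
    win <- random_seq(28)
    got <- duplex_score(trf, win)
    best <- -Inf
    for (off in 0:8) {
      stretch <- substr(win, off + 1, off + 20)
      # score this register from first principles
      tb <- strsplit(trf, "")[[1]]
      sb <- rev(strsplit(stretch, "")[[1]])
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      sc <- 0
      for (j in 1:20) {
        wc <- comp[tb[j]] == sb[j]
        gu <- (tb[j] == "G" & sb[j] == "T") | (tb[j] == "T" & sb[j] == "G")
        s <- if (wc) 5 else if (gu) 1 else -3
        if (j >= 2 && j <= 8) s <- 2 * s
        sc <- sc + s
      }
      best <- max(best, sc)
    }
    expect_equal(unname(got["score"]), best)
  }
})

test_that("predict_targets applies the dual seed + duplex filter", {
  set.seed(21)
  trf <- random_seq(36)
  planted_genes <- sprintf("gene%04d", c(3, 11, 24, 37, 42))
  db <- make_annotation_db(50, 3, utr_length = 400,
                           planted_sites = setNames(
                             rep(list(trf), 5), planted_genes),
                           seed = 9)
  hits <- predict_targets(c(tRF1 = trf), db$utr)
  expect_setequal(hits$gene_id, planted_genes)  # exactly the planted 5
  expect_true(all(hits$duplex_score >= 150 & hits$duplex_energy <= -20))
  expect_true(all(hits$seed_type %in% c("7mer", "8mer")))

  # a 7mer seed alone, weak elsewhere, fails the energy filter
  seed_only <- paste0(strrep("C", 100),
                      trfheritance:::revcomp(substr(trf, 2, 8)),
                      strrep("C", 100))
  none <- predict_targets(c(tRF1 = trf), c(geneX = seed_only))
  expect_equal(nrow(none), 0)

  # threshold monotonicity: relaxing thresholds never removes a hit
  relaxed <- predict_targets(c(tRF1 = trf), db$utr,
                             score_min = 100, energy_max = -10)
  expect_true(all(paste(hits$trf_id, hits$gene_id) %in%
                    paste(relaxed$trf_id, relaxed$gene_id)))

  expect_error(predict_targets(c(tRF1 = trf), character(0)), "empty")
})

test_that("enrich computes exact hypergeometric over-representation", {
  universe <- c("g1", "g2", "g3", "g4")
  ann <- data.frame(gene_id = c("g1", "g2", "g1", "g2", "g3", "g4"),
                    term_id = c("T1", "T1", "T2", "T2", "T2", "T2"))
  # N=4, K=2, n=2, k=2 -> p = 1/6
  res <- enrich(c("g1", "g2"), ann, universe, fdr_max = 1.01)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(t1$k, 2)
  expect_true(all(res$fdr >= res$p_value))

  # term equal to the universe: p = 1, never below any fdr_max < 1
  t2 <- attr(enrich(c("g1", "g2"), ann, universe, fdr_max = 0.25),
             "full")
  expect_equal(t2$p_value[t2$term_id == "T2"], 1)
  expect_false("T2" %in% enrich(c("g1", "g2"), ann, universe)$term_id)

  expect_error(enrich("g9", ann, universe), "universe")
})

test_that("enrich recovers planted enrichment and is super-uniform", {
  db <- make_annotation_db(100, 5, genes_per_term_range = c(15, 15),
                           seed = 31)
  target_term <- "TERM003"
  members <- db$annotation$gene_id[db$annotation$term_id == target_term]
  res <- enrich(members[1:10], db$annotation, db$genes, fdr_max = 1.01)
  expect_equal(res$term_id[1], target_term)   # smallest p first

  # random queries: P(p <= a) <= a approximately (Monte-Carlo)
  set.seed(8)
  pmin_draws <- vapply(1:200, function(i) {
    q <- sample(db$genes, 10)
    min(attr(enrich(q, db$annotation, db$genes, fdr_max = 1.01),
             "full")$p_value)
  }, numeric(1))
  # with 5 correlated terms, P(min p < 0.05) stays near/below 5 * 0.05
  expect_lt(mean(pmin_draws < 0.05), 0.3)
  expect_lt(mean(pmin_draws < 0.01), 0.1)
})
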