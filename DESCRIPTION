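Package: trfheritance
Title: Sperm tRNA-Derived Fragment Quantification and Cross-Generational
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for small-RNA sequencing studies of
    sperm tRNA-derived fragments (tRFs): adapter trimming, quality and
    size filtering, ungapped alignment to a tRNA reference with weighted
    apportionment of multi-mapping reads, TPM normalization,
    two-condition differential expression with Benjamini-Hochberg
    correction, cross-generation overlap analysis, seed-match plus
    duplex-energy target prediction with hypergeometric term enrichment,
    and phenotype statistics (trapezoid-rule insulin-tolerance AUC,
    ANOVA, Kaplan-Meier/log-rank).  A synthetic-data generator emulates
    the statistical structure of sperm small-RNA libraries (dominant
    isoacceptor composition, intra-family multi-mapping, planted
    fold-changes) with full ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    survival,
    utils,
    yaml,
    jsonlite
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
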