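---
title: "Methods: sperm tRF quantification, differential expression and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sperm tRF quantification, differential expression and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfheritance)
```

# Scope and model

`trfheritance` analyses small-RNA sequencing of mature sperm, where
30–45 nt tRNA-derived fragments (tRFs) dominate the library. The
scientific question it serves is cross-generational: which tRF species
shift with a paternal exposure in fathers (F0) and again in their sons
(F1), with a consistent direction of change?

Three properties of the data shape the design:

1. **Multi-mapping.** tRNAs of one isoacceptor family differ at only a
   few percent of positions, so a 30–45 nt fragment frequently aligns
   equally well to several reference tRNAs ("shared reads").
2. **Skewed composition.** A small number of species (GlyGCC, GluCTC)
   carry most of the reads — on the order of 70% combined — so
   abundance analysis is effectively compositional.
3. **Small n.** Sperm RNA-seq designs run 3–4 replicates per group, so
   the differential test must behave sensibly at tiny sample sizes.

Alignment here is against a closed tRNA reference rather than a whole
genome. This is the package's one structural simplification: the
quantification target is tRNA species, and a closed reference makes
every stage exactly testable at desk scale. Consequences: reads from
non-tRNA loci would simply be unmapped, and genomic-context annotation
is out of scope.

# The quantification stage

## Preprocessing

Three operators compose, in small-RNA convention order:

* `trim_adapter()` removes the longest 3′ suffix of a read matching a
  prefix of the adapter with at least `min_overlap` (default 3) bases
  and mismatch rate at most `max_mismatch_rate` (default 0.1). Matching
  is ungapped. This is a documented, contract-level stand-in for
  general-purpose read trimmers: the named tools' exact parameterization
  is not reproduced — what downstream stages require is the contract
  (adapter gone, qualities in lockstep), not a particular tool.
* `quality_pass()` requires every sliding window of `window` bases
  (default 4) to hold mean Phred ≥ `min_mean_q` (default 15), and
  length ≥ `min_len` (default 15). These defaults are the field's
  common sliding-window convention.
* `size_select()` keeps reads of 30–45 nt, **both ends inclusive** —
  the gel excision window that defines a tRF in this context.

Reads are never 5′-trimmed. Preprocessing an already-clean library is
the identity, and the stage counters satisfy the accounting identity
`n_input = n_quality_failed + (reads kept or removed by size selection)`
exactly; both are tested.

## Alignment and the weighted-read formula

`align_read()` slides the read ungapped across every offset of every
reference (sense strand only; small-RNA libraries are stranded and tRFs
are sense fragments), scores each placement by match count, and reports
per reference the best offset as a percentage score,
`100 × matches / read length`, subject to `min_score_percent` (default
85). Ties within one reference resolve to the smallest start;
coordinates are 0-based internally. The substitution-only error model of
the simulator (below) keeps this exact ungapped scan sufficient — there
are no indels to chase.

`classify()` partitions reads: no hits → unmapped; one reference →
unique; otherwise shared across all references within
`best_margin_percent` (default 0, i.e. only exact score ties) of the
best hit.

`weighted_counts()` then computes, per reference,
`weighted = unique + shared contribution`, with the score term in two
modes because the verbatim formula
(`weighted reads = unique reads + alignment score % * shared reads`)
is ambiguous about normalization:

* **literal** (default): each shared read adds `score%/100` to *every*
  member of its shared set. A read tied at 100% across two references
  contributes total mass 2. This is the formula applied verbatim.
* **normalized**: each shared read's contributions are normalized over
  its shared set, so every mapped read contributes mass exactly 1 and
  `Σ_r weighted(r) = n_mapped` holds to 1e-9 (tested as an exact
  invariant).

The literal reading over-counts families in proportion to their share
of multi-mapping reads: if one family's members happen to be identical
over the fragment window more often than another's, its composition
fraction is inflated. This is a real property of the verbatim formula,
not an implementation artifact; the test suite asserts binomial-level
composition recovery for `normalized` mode and a bias-aware bound
(the shared-read fraction) for `literal` mode. Since differential
expression compares the same species across samples, the literal bias
largely cancels there; composition summaries should use `normalized`.

# Expression analysis

`tpm_normalize()` scales each library to 10⁶. The default is
counts-per-million of weighted counts (`length_normalize = FALSE`):
classic TPM divides by transcript length, but all tRFs live in one
narrow 30–45 nt window, so length-rate normalization adds nothing and
invites a second ambiguity (length of the tRNA or of the fragment?).
Classic TPM remains available by flag, using reference lengths.

`de_test()` compares two groups per species on log₂(TPM+1):

* `welch_log` (default): two-sided Welch t-test. Chosen as the default
  because it is the standard screen-level test; its fragility at
  n = 3–4 motivates the alternative.
* `exact_permutation`: the exact permutation distribution of the mean
  log₂ difference over all `choose(nA+nB, nA)` relabelings (20 at 3v3,
  70 at 4v4) — no distributional assumptions, granularity limited by
  the design size. The implementation is checked against full
  enumeration.

Multiple testing uses Benjamini–Hochberg (the field convention for
expression screens); whether the α = 0.05 cut applies to q-values
(default) or raw p-values is configurable (`use_raw_p`), since
published method descriptions of this analysis type are frequently
ambiguous on that point. A species with zero variance in both groups
and equal means gets p = 1 by convention.

`overlap_analysis()` intersects two comparisons' significant sets and
**requires the same direction** in both; a species up in F0 and down in
F1 does not count. `composition_summary()` ranks species by grand mean
fraction (ties broken by label) and reports combined top-k fractions.

# Target prediction and enrichment

For selected tRFs, `predict_targets()` retains a gene only if it passes
both predictors:

* `seed_sites()`: an exact Watson–Crick complement in the 3′UTR of tRF
  positions 2–8 (7mer; with an adjacent A, 8mer). The microRNA seed
  convention is transplanted to tRFs as a deliberate, documented choice
  — which tRF subsequence actually nucleates target recognition is an
  open question, and the 5′ end is the configurable default.
* `duplex_score()`: best ungapped antiparallel register with per-position
  scores +5 (Watson–Crick), +1 (G:U wobble), −3 (mismatch), positions
  2–8 doubled; energies sum simplified pair contributions
  (G:C −3.0, A:T −2.0, G:U −1.0 kcal/mol). A gene passes when some
  register clears **both** score ≥ 150 and energy ≤ −20.

This scorer is an explicit, simplified stand-in for miRanda-style duplex
evaluation with Vienna-style energies; the threshold values are
calibrated to *this* scorer's scale and are not comparable to any other
tool's scale. The dual filter is monotone in its thresholds (relaxing
them never removes a hit; tested as a property).

`enrich()` is a one-sided hypergeometric over-representation test per
term, BH-corrected across terms, reported below FDR 0.25. It is exact
(`k` successes out of `n` draws from `K` of `N`), verified against a
hand-counted combinatorial instance.

# Phenotype statistics

`trapezoid_auc()` integrates glucose–time series sampled at 0, 3, 6, 9,
12 and 30 minutes (the insulin-tolerance schedule) by the trapezoid
rule, in mg/dL·min. `oneway_anova()`/`twoway_anova()` are classical
fixed-effects decompositions (delegating to `stats::aov`); the post-hoc
analysis is Holm-adjusted pairwise Welch tests — well-defined and
conservative without extra distributional machinery. Two-way designs
must be balanced and complete (≥ 2 replicates per cell); unbalanced
designs are refused rather than silently type-III'd. An effect whose
sum of squares vanishes is reported as F = 0, p = 1 (the 0/0 case when
residuals also vanish). Tumor incidence uses Kaplan–Meier with right
censoring and the standard two-group log-rank statistic via the
`survival` package, cross-checked against hand-computed risk tables.
Repeated-measures modeling of tumor growth is out of scope; per-timepoint
two-way ANOVA on a balanced design is the provided simplification.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions every statistical claim in this package is made under.

* **Reference** (`make_reference()`): 7 families × 3 members, family
  length 70–90 nt, within-family expected pairwise identity 0.95 by
  i.i.d. substitutions from a random family ancestor (the substitution
  rate solves `(1−m)² + m²/3 = identity`; targets below 0.25, the
  unrelated-sequence identity, are clamped). Distinct random ancestors
  keep cross-family identity near 25%, so families never cross-map at
  the 85% score threshold while members within a family do — the
  multi-mapping structure the weighted-count stage exists for.
* **Libraries** (`simulate_library()`): composition
  GlyGCC 0.40, GluCTC 0.30, ValTAC 0.03, SerCGA 0.03, ArgCCG 0.08,
  ArgTCG 0.08, SeCTCA 0.08 — the dominant pair at a combined 0.70.
  Fragments are 5′-anchored prefixes (sperm tRFs are predominantly 5′
  fragments; fragment origin is otherwise unstated in this study
  design, so a `uniform_start` flag exists), length uniform in 30–45
  nt, full 3′ adapter appended, substitution errors at 0.001/base,
  Phred 32–40 qualities. Depth defaults to 2×10⁴ reads — enough for
  binomial composition error well under a percentage point, small
  enough that a full 16-library pipeline runs in well under a minute.
* **Planted effects**: fold-changes ValTAC ×4, SerCGA ×4, ArgCCG,
  ArgTCG, SeCTCA ×0.25 applied to the treated condition and
  renormalized. The effect/composition pairing is **mass-balanced**:
  the probability mass gained by the up-regulated pair
  (2 × 0.03 × 3 = 0.18) equals the mass lost by the down-regulated
  trio (3 × 0.08 × 0.75 = 0.18), so under renormalization the
  unperturbed species — in particular the dominant pair — keep their
  proportions exactly. Without this balance, compositional closure
  would make GlyGCC and GluCTC spuriously differential in both
  generations and the direction-consistent overlap would exceed the
  five planted species; with it, exactly the planted five are
  recoverable. The 4-fold magnitude puts the planted effects far above
  the multinomial noise floor at n = 4, which is what a recovery
  fixture should do.
* **Count-level twin** (`simulate_counts()`): multinomial draws from
  the same composition/effect model, skipping read synthesis. The
  calibration experiments that need hundreds of datasets (type-I error
  over 200 null datasets, overlap recovery over 20 reseeds) run at this
  level; the read-level path is exercised end-to-end by the composition
  recovery run and the pipeline tests. This split keeps the whole suite
  fast without weakening what each experiment measures — the DE stage
  consumes count matrices regardless of how they were produced.
* **Seeds**: a master seed expands to child streams as
  `child_seed(master, k) = (master + 1000003·k) mod (2³¹−1)`, so adding
  a library never perturbs earlier ones; identical config + seed gives
  byte-identical FASTQ and truth output (tested).

What the generator does **not** emulate: RNA modifications (a major
real-world complication for tRF sequencing chemistry), ligation and PCR
bias, indels, partial 3′ adapters (unless flagged), genome-scale
references, and any correlation structure between species beyond
multinomial closure. Passing tests therefore demonstrate correctness of
the pipeline's logic under its stated model, not robustness to every
artifact of real sperm libraries.

Phenotype fixtures: glucose series follow
`baseline − dip·(t/12)·e^(1−t/12)` plus Gaussian noise (nadir near
12 min, partial recovery by 30 min); tumor-onset times are exponential
per group, right-censored at 20 weeks of monitoring.

# Pipeline orchestration

`run_pipeline()` executes simulate → preprocess → quantify → de →
overlap from one flat configuration (YAML/JSON file or list), with every
stage's effective settings echoed into `manifest.json`, so each of the
ambiguity resolutions above (literal/normalized, welch/permutation,
raw/corrected p, CPM/classic TPM) is recorded per run. A stage failure
halts with a stage-named error; a preprocess section that states no
adapter anywhere is rejected as a configuration error. This package is a
library, not a shell tool: its users drive it from R, so the
command-line surface is `run_pipeline()` plus `scripts/acceptance.R`
rather than a standalone executable.

# Problem sizes and numerical choices

Default analysis scale: 7 species, 21 reference tRNAs, 2×10⁴ reads per
library, 4 replicates per group. The test suite's heavier experiments
use 20 reseeds (overlap recovery) and 200 null datasets (type-I error)
at count level, and 50 regenerations for the reference-identity
Monte-Carlo. Tolerances: conservation is asserted to 1e-9; composition
recovery to binomial tolerance at the stated depths; TPM column sums to
1e-3 absolute. Ties: alignment offsets by smallest start, composition
ranks by species label, seed-site types by strongest class.

# Known limitations

* The tRNA-reference (not genome) alignment excludes non-tRF small RNAs
  by construction rather than by annotation.
* The duplex scorer and its thresholds are package-defined scales, not
  reconstructions of any published tool's internals.
* Welch's t at n = 3–4 is fragile; the permutation test's granularity
  (minimum two-sided p of 1/10 at 3v3 treating the observed labeling as
  one relabeling) caps how small its p-values can be. Neither problem
  has a free lunch at these design sizes.
* Repeated-measures and mixed-effects phenotype models are out of scope.
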