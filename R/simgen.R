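#' Canonical isoacceptor labels used by the simulator
#'
#' The seven isoacceptor families the default fixtures are built from:
#' the two dominant sperm tRF species (GlyGCC, GluCTC) plus the five
#' species perturbed across generations in the study design this package
#' emulates (ValTAC, SerCGA up; ArgCCG, ArgTCG, SeCTCA down).
#' @export
TRF_ISOACCEPTORS <- c("GlyGCC", "GluCTC", "ValTAC", "SerCGA",
                      "ArgCCG", "ArgTCG", "SeCTCA")

new_trna_reference <- function(ref_id, isoacceptor, sequence) {
  stopifnot(!anyDuplicated(ref_id))
  sequence <- toupper(sequence)
  check_alphabet(sequence, "reference sequence")
  df <- data.frame(ref_id = ref_id, isoacceptor = isoacceptor,
                   sequence = sequence, length = nchar(sequence),
                   stringsAsFactors = FALSE)
  class(df) <- c("trna_reference", "data.frame")
  df
}

# Per-base substitution rate m such that two sequences independently
# mutated from a common ancestor have expected pairwise identity t:
#   (1-m)^2 + m^2/3 = t  (both unmutated, or both mutated to the same
#   of 3 alternative bases).  Real solutions need t >= 1/4 (the identity
#   of unrelated sequences); below that the target is unreachable.
mutation_rate_for_identity <- function(t) {
  if (t >= 1) return(0)
  t <- max(t, 0.25)
  (2 - sqrt(4 - (16 / 3) * (1 - t))) / (8 / 3)
}

#' Generate a synthetic tRNA reference with family structure
#'
#' Families model isoacceptors: each family has a random ancestor
#' sequence and `members_per_family` members derived from it by i.i.d.
#' substitutions, tuned so the expected pairwise within-family identity
#' equals `within_family_identity`.  High within-family identity is what
#' makes reads multi-map ("shared reads") downstream; distinct random
#' ancestors keep families well separated (~25% cross-family identity).
#'
#' @param n_families Number of isoacceptor families (>= 1).
#' @param members_per_family Members per family (>= 1).
#' @param within_family_identity Target expected pairwise identity within
#'   a family, in `[0, 1]`; values below 0.25 (identity of unrelated
#'   sequences under this substitution model) are clamped to 0.25.
#' @param length_range Integer pair; each family's length is drawn
#'   uniformly from this range (default 70--90 nt, mature tRNA scale).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param isoacceptors Optional family labels; defaults to
#'   [TRF_ISOACCEPTORS] (recycled with numeric suffixes when
#'   `n_families` exceeds the label pool).
#' @return A `trna_reference` data.frame with columns `ref_id`,
#'   `isoacceptor`, `sequence`, `length`; ref_ids are
#'   `<isoacceptor>_<member>`.
#' @examples
#' ref <- make_reference(2, 3, 0.9, seed = 1)
#' table(ref$isoacceptor)
#' @export
make_reference <- function(n_families, members_per_family,
                           within_family_identity,
                           length_range = c(70, 90), seed = 1,
                           isoacceptors = NULL) {
  if (n_families < 1 || members_per_family < 1)
    stop("n_families and members_per_family must be >= 1", call. = FALSE)
  if (within_family_identity < 0 || within_family_identity > 1)
    stop("within_family_identity must lie in [0, 1]", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 60 || length_range[2] > 100)
    stop("length_range must be (min, max) within [60, 100]", call. = FALSE)

  if (is.null(isoacceptors)) {
    isoacceptors <- if (n_families <= length(TRF_ISOACCEPTORS)) {
      TRF_ISOACCEPTORS[seq_len(n_families)]
    } else {
      make.unique(rep(TRF_ISOACCEPTORS, length.out = n_families), sep = "")
    }
  }
  stopifnot(length(isoacceptors) == n_families)

  m <- mutation_rate_for_identity(within_family_identity)
  set.seed(child_seed(seed, 0L))
  out <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    len <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(length_range[1]:length_range[2], 1)
    ancestor <- sample(DNA_BASES, len, replace = TRUE)
    members <- vapply(seq_len(members_per_family), function(j) {
      s <- ancestor
      hit <- stats::runif(len) < m
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    out[[f]] <- data.frame(
      ref_id = paste0(isoacceptors[f], "_", seq_len(members_per_family)),
      isoacceptor = isoacceptors[f],
      sequence = members, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  new_trna_reference(out$ref_id, out$isoacceptor, out$sequence)
}

#' Simulation configuration for sperm tRF libraries
#'
#' Defaults encode the study conditions the package emulates: seven
#' isoacceptor families with GlyGCC + GluCTC at a combined 70% of reads,
#' fragment lengths uniform in 30--45 nt, 4 replicates per group, and
#' mass-balanced 4-fold planted effects on five species (ValTAC and
#' SerCGA up, ArgCCG, ArgTCG and SeCTCA down) applied to the treated
#' condition.  The effects are mass-balanced against the default
#' composition (the up-weight gained equals the down-weight lost) so the
#' unperturbed dominant species keep their proportions under
#' compositional renormalization.
#'
#' @param composition Named proportions per isoacceptor; must sum to 1.
#' @param depth Reads per library (>= 0).
#' @param length_window Fragment-length window (min, max) in nt, within
#'   `[15, 60]`; both ends inclusive.
#' @param adapter 3' adapter sequence appended to every read.
#' @param error_rate Per-base substitution probability.
#' @param effects Named fold-changes (> 0) applied multiplicatively to
#'   the composition of libraries whose condition is in `treated`.
#' @param replicates Libraries per group.
#' @param treated Condition labels that carry the effects.
#' @param uniform_start If `TRUE` fragments start uniformly along the
#'   tRNA; default `FALSE` = 5'-anchored fragments (sperm tRFs are
#'   predominantly 5' halves).
#' @param partial_adapter If `TRUE`, a third of reads receive a randomly
#'   truncated adapter (exercises trimming edge cases).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(composition = c(GlyGCC = 0.40, GluCTC = 0.30,
                                       ValTAC = 0.03, SerCGA = 0.03,
                                       ArgCCG = 0.08, ArgTCG = 0.08,
                                       SeCTCA = 0.08),
                       depth = 20000,
                       length_window = c(30, 45),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       error_rate = 0.001,
                       effects = c(ValTAC = 4, SerCGA = 4, ArgCCG = 0.25,
                                   ArgTCG = 0.25, SeCTCA = 0.25),
                       replicates = 4,
                       treated = "OID",
                       uniform_start = FALSE,
                       partial_adapter = FALSE) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector", call. = FALSE)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must be >= 0 and sum to 1", call. = FALSE)
  if (length(effects) && (is.null(names(effects)) || any(effects <= 0)))
    stop("effects must be named fold-changes > 0", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (length(length_window) != 2 || length_window[1] > length_window[2] ||
      length_window[1] < 15 || length_window[2] > 60)
    stop("length_window must be (min, max) within [15, 60]", call. = FALSE)
  if (nchar(adapter) > 0) check_alphabet(adapter, "adapter")
  structure(list(composition = composition, depth = depth,
                 length_window = as.integer(length_window),
                 adapter = toupper(adapter), error_rate = error_rate,
                 effects = effects, replicates = as.integer(replicates),
                 treated = treated, uniform_start = uniform_start,
                 partial_adapter = partial_adapter),
            class = "sim_config")
}

# Effect-adjusted, renormalized sampling weights for one condition.
condition_weights <- function(config, condition) {
  w <- config$composition
  if (condition %in% config$treated && length(config$effects)) {
    unknown <- setdiff(names(config$effects), names(w))
    if (length(unknown))
      stop("effects reference unknown isoacceptor: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    w[names(config$effects)] <- w[names(config$effects)] * config$effects
  }
  w / sum(w)
}

#' Simulate one sperm small-RNA FASTQ library with ground truth
#'
#' Each read is a contiguous fragment of one reference sequence
#' (5'-anchored unless `config$uniform_start`), length uniform in the
#' configured window (truncated to the tRNA length), with the 3' adapter
#' appended and i.i.d. substitution errors applied across the whole read.
#' Source isoacceptors are sampled proportional to the configured
#' composition, multiplied by the planted fold-changes and renormalized
#' when `condition` is a treated label; the member within a family is
#' uniform.
#'
#' @param ref A `trna_reference` from [make_reference()].
#' @param config A [sim_config()].
#' @param condition Condition label for this library (e.g. "CO", "OID").
#' @param seed Integer seed; byte-identical output for identical inputs.
#' @param sample_id Prefix used for read ids.
#' @return A list with `reads` (data.frame `read_id`, `sequence`,
#'   `quality` — write with [write_fastq()]) and `truth` (one row per
#'   read: `read_id`, `source_ref_id`, `source_isoacceptor`,
#'   `fragment_start` (0-based), `fragment_length`), plus attributes
#'   `realized_composition` and `planted_effects` on `truth`.
#' @export
simulate_library <- function(ref, config, condition, seed,
                             sample_id = condition) {
  stopifnot(inherits(ref, "trna_reference"), inherits(config, "sim_config"))
  missing_iso <- setdiff(names(config$composition), ref$isoacceptor)
  if (length(missing_iso))
    stop("composition references isoacceptors absent from the reference: ",
         paste(missing_iso, collapse = ", "), call. = FALSE)
  n <- config$depth
  empty <- function() {
    list(reads = data.frame(read_id = character(), sequence = character(),
                            quality = character(), stringsAsFactors = FALSE),
         truth = structure(
           data.frame(read_id = character(), source_ref_id = character(),
                      source_isoacceptor = character(),
                      fragment_start = integer(), fragment_length = integer(),
                      stringsAsFactors = FALSE),
           realized_composition = numeric(0),
           planted_effects = config$effects))
  }
  if (n == 0) return(empty())

  set.seed(seed)
  w <- condition_weights(config, condition)
  iso <- sample(names(w), n, replace = TRUE, prob = w)

  # uniform member within the sampled family
  fam_members <- split(seq_len(nrow(ref)), ref$isoacceptor)
  ridx <- vapply(iso, function(a) {
    mem <- fam_members[[a]]
    if (length(mem) == 1) mem else mem[sample.int(length(mem), 1)]
  }, integer(1))

  ref_len <- ref$length[ridx]
  lw <- config$length_window
  frag_len <- pmin(sample(lw[1]:lw[2], n, replace = TRUE), ref_len)
  frag_start <- if (config$uniform_start) {
    vapply(seq_len(n), function(i)
      sample.int(ref_len[i] - frag_len[i] + 1L, 1) - 1L, integer(1))
  } else rep(0L, n)
  frag <- substr(ref$sequence[ridx], frag_start + 1L, frag_start + frag_len)

  adapter <- config$adapter
  if (nzchar(adapter)) {
    ad <- rep(adapter, n)
    if (config$partial_adapter) {
      cut <- sample.int(n, size = floor(n / 3))
      ad[cut] <- substr(adapter, 1L,
                        sample.int(nchar(adapter), length(cut), replace = TRUE))
    }
    seqs <- paste0(frag, ad)
  } else seqs <- frag

  # substitution errors across the full read (fragment + adapter)
  if (config$error_rate > 0) {
    lens <- nchar(seqs)
    nerr <- stats::rbinom(n, lens, config$error_rate)
    for (i in which(nerr > 0)) {
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(lens[i], nerr[i])
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(DNA_BASES, b), 1), character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }

  # high, mildly variable Phred+33 qualities (Q32-Q40)
  lens <- nchar(seqs)
  qall <- sample(32:40, sum(lens), replace = TRUE) + 33L
  qual <- vapply(split(qall, rep.int(seq_len(n), lens)),
                 function(v) rawToChar(as.raw(v)), character(1),
                 USE.NAMES = FALSE)

  read_id <- sprintf("%s_read%06d", sample_id, seq_len(n))
  truth <- data.frame(read_id = read_id, source_ref_id = ref$ref_id[ridx],
                      source_isoacceptor = ref$isoacceptor[ridx],
                      fragment_start = frag_start,
                      fragment_length = frag_len,
                      stringsAsFactors = FALSE)
  attr(truth, "realized_composition") <-
    table(factor(iso, levels = names(w))) / n
  attr(truth, "planted_effects") <- config$effects
  list(reads = data.frame(read_id = read_id, sequence = seqs, quality = qual,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a count-level tRF dataset (no reads)
#'
#' Draws per-library isoacceptor counts directly from the multinomial
#' model underlying [simulate_library()] — the same composition and
#' planted-effect structure without read synthesis or alignment.  Used
#' for statistical calibration experiments (type-I error, power,
#' overlap recovery over many reseeds) where simulating sequences would
#' only add run time, not information.
#'
#' @param config A [sim_config()].
#' @param conditions Character vector of condition labels, one library
#'   per element (e.g. `rep(c("CO", "OID"), each = 4)`).
#' @param seed Integer seed.
#' @return Integer matrix, isoacceptors x libraries, with condition
#'   labels in `colnames` suffixed by replicate.
#' @export
simulate_counts <- function(config, conditions, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  m <- vapply(conditions, function(cond) {
    w <- condition_weights(config, cond)
    as.integer(stats::rmultinom(1, config$depth, w))
  }, integer(length(config$composition)))
  rownames(m) <- names(config$composition)
  colnames(m) <- make.unique(conditions, sep = "_")
  m
}
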