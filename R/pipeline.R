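#' Run the full tRF analysis pipeline from a configuration
#'
#' Orchestrates simulate -> preprocess -> quantify -> de -> overlap on a
#' synthetic experiment (two conditions per generation), writing all
#' intermediate tables under `outdir` and returning a run manifest.
#' Stages execute in order; a failure halts the run with a stage-named
#' error.  Reruns with an identical configuration and seed are
#' bit-identical.
#'
#' The configuration is a YAML (or JSON) file, or an equivalent named
#' list, with optional per-stage sections `simulate`, `preprocess`,
#' `quantify`, `de`; every omitted setting falls back to the package
#' default for that stage, and all effective settings are echoed into
#' the manifest.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param outdir Output directory (created if needed); overrides any
#'   `outdir` in the config.
#' @param seed Master seed; overrides any `seed` in the config.
#' @return A `run_manifest` list: `config` (effective settings),
#'   `seed`, `stages` (per-stage record counts and paths), `results`
#'   (count matrix, TPM, per-generation `de_result`s, overlap report).
#'   The manifest (minus in-memory results) is serialized to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("trfrun"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- seed %||% config$seed %||% 1L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sim <- config$simulate %||% list()
  pp <- config$preprocess %||% list()
  qt <- config$quantify %||% list()
  de <- config$de %||% list()

  sc_args <- sim[intersect(names(sim),
                           names(formals(sim_config)))]
  sc_args$composition <- unlist(sc_args$composition) %||% NULL
  sc_args$effects <- unlist(sc_args$effects) %||% NULL
  sc_args <- sc_args[!vapply(sc_args, is.null, logical(1))]
  cfg <- do.call(sim_config, sc_args)

  if (!is.null(config$preprocess) && is.null(pp$adapter) &&
      is.null(sim$adapter) && !length(sc_args$adapter))
    stop("config error: missing key 'preprocess.adapter'", call. = FALSE)
  adapter <- pp$adapter %||% cfg$adapter

  generations <- sim$generations %||% c("F0", "F1")
  conditions <- sim$conditions %||% c("CO", "OID")
  replicates <- cfg$replicates

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  manifest <- list(config = list(simulate = cfg[setdiff(names(cfg), "")],
                                 preprocess = pp, quantify = qt, de = de),
                   seed = seed, stages = list())

  ## simulate ----------------------------------------------------------
  ref <- stage("simulate", {
    r <- make_reference(sim$n_families %||% length(cfg$composition),
                        sim$members_per_family %||% 3,
                        sim$within_family_identity %||% 0.95,
                        unlist(sim$length_range) %||% c(70, 90),
                        seed = child_seed(seed, 0L))
    write_reference_fasta(r, file.path(outdir, "reference.fa"))
    r
  })
  libs <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, generation = generations,
                      stringsAsFactors = FALSE)
  libs$sample_id <- sprintf("%s_%s_%d", libs$generation, libs$condition,
                            libs$replicate)
  sims <- stage("simulate", lapply(seq_len(nrow(libs)), function(i) {
    simulate_library(ref, cfg, libs$condition[i],
                     seed = child_seed(seed, i),
                     sample_id = libs$sample_id[i])
  }))
  for (i in seq_len(nrow(libs))) {
    write_fastq(sims[[i]]$reads,
                file.path(outdir, paste0(libs$sample_id[i], ".fastq")))
    write_tsv(sims[[i]]$truth,
              file.path(outdir, paste0(libs$sample_id[i], ".truth.tsv")))
  }
  manifest$stages$simulate <- list(
    n_libraries = nrow(libs), depth = cfg$depth,
    reads_out = sum(vapply(sims, function(s) nrow(s$reads), numeric(1))))

  if (identical(config$stages, "simulate")) {
    manifest$results <- list(reference = ref, libraries = libs)
    write_manifest(manifest, outdir)
    return(invisible(structure(manifest, class = "run_manifest")))
  }

  ## preprocess --------------------------------------------------------
  cleaned <- stage("preprocess", lapply(sims, function(s)
    preprocess_fastq(s$reads, adapter = adapter,
                     min_overlap = pp$min_overlap %||% 3,
                     max_mismatch_rate = pp$max_mismatch_rate %||% 0.1,
                     window = pp$window %||% 4,
                     min_mean_q = pp$min_q %||% 15,
                     min_len = pp$min_len %||% 15,
                     min_nt = pp$min_nt %||% 30,
                     max_nt = pp$max_nt %||% 45)))
  manifest$stages$preprocess <- list(
    reads_in = sum(vapply(cleaned, `[[`, numeric(1), "n_input")),
    reads_out = sum(vapply(cleaned, `[[`, numeric(1), "n_size_selected")))

  ## quantify ----------------------------------------------------------
  mode <- qt$mode %||% "literal"
  tables <- stage("quantify", lapply(cleaned, function(cl)
    quantify_sample(cl$reads, ref, mode = mode,
                    min_score_percent = qt$min_score %||% 85,
                    best_margin_percent = qt$best_margin %||% 0)))
  names(tables) <- libs$sample_id
  counts <- count_matrix(tables, collapse = qt$collapse %||% "by_isoacceptor",
                         ref = ref)
  write_tsv(data.frame(species = rownames(counts), counts,
                       check.names = FALSE),
            file.path(outdir, "count_matrix.tsv"))
  manifest$stages$quantify <- list(
    reads_in = manifest$stages$preprocess$reads_out,
    mode = mode,
    reads_mapped = sum(vapply(tables, function(t)
      attr(t, "totals")[["n_mapped"]], numeric(1))))

  ## de + overlap ------------------------------------------------------
  lengths <- stats::setNames(ref$length, ref$ref_id)
  tpm <- stage("de", tpm_normalize(counts,
                                   length_normalize = isTRUE(de$length_normalize)))
  write_tsv(data.frame(species = rownames(tpm), tpm, check.names = FALSE),
            file.path(outdir, "tpm_matrix.tsv"))
  group <- stats::setNames(paste(libs$generation, libs$condition, sep = "_"),
                           libs$sample_id)
  de_res <- stage("de", lapply(generations, function(gen) {
    r <- de_test(tpm[, grepl(paste0("^", gen, "_"), group), drop = FALSE],
                 group[grepl(paste0("^", gen, "_"), group)],
                 group_a = paste0(gen, "_", conditions[1]),
                 group_b = paste0(gen, "_", conditions[2]),
                 alpha = de$alpha %||% 0.05,
                 method = de$method %||% "welch_log",
                 use_raw_p = isTRUE(de$use_raw_p))
    write_tsv(r, file.path(outdir, paste0("de_", gen, ".tsv")))
    r
  }))
  names(de_res) <- generations
  manifest$stages$de <- list(n_species = nrow(counts),
                             method = de$method %||% "welch_log",
                             alpha = de$alpha %||% 0.05)

  overlap <- NULL
  if (length(generations) >= 2) {
    overlap <- stage("overlap",
                     overlap_analysis(de_res[[1]], de_res[[2]]))
    write_tsv(overlap$overlap, file.path(outdir, "overlap.tsv"))
    manifest$stages$overlap <- list(n_overlap = overlap$n_overlap,
                                    n_up_shared = overlap$n_up_shared,
                                    n_down_shared = overlap$n_down_shared)
  }

  manifest$results <- list(reference = ref, libraries = libs,
                           counts = counts, tpm = tpm, de = de_res,
                           overlap = overlap)
  write_manifest(manifest, outdir)
  invisible(structure(manifest, class = "run_manifest"))
}

write_manifest <- function(manifest, outdir) {
  slim <- manifest[c("config", "seed", "stages")]
  slim$config$simulate <- lapply(slim$config$simulate, unclass)
  jsonlite::write_json(slim, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}
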