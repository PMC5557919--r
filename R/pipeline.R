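#' Assemble and validate a pipeline configuration
#'
#' A single document (built in code or loaded from YAML with
#' [read_pipeline_config()]) configures the whole chain
#' simulate -> induction -> abundance -> categorize -> annotate.
#'
#' The significance band must be given in exactly one of two forms:
#' explicit bounds (`band = list(lower = 0.785, upper = 1.274)`) or a
#' construction recipe (`band = list(sd_log = ..., level = ...)`).
#'
#' @param seed Integer seed (mandatory; drives the simulation stage).
#' @param out_dir Output directory for stage artifacts.
#' @param sim Named list of [sim_config()] overrides (e.g. `n_mutants`).
#' @param gate_percentile Per-well lower scatter percentile removed by
#'   gating (ignored when `gate_threshold` is set).
#' @param gate_threshold Optional absolute scatter cutoff.
#' @param min_events Minimum gated events per well.
#' @param band Band specification (see Details).
#' @param anchor_strain,wild_type Strain ids for batch anchoring and the
#'   ratio denominators.
#' @param reference_batch Optional reference batch label.
#' @param digits Display precision used in printed summaries (stored
#'   values are never rounded).
#' @return A validated list of class `alascan_pipeline_config`.
#' @export
#' @examples
#' pipeline_config(seed = 1, out_dir = tempdir(), sim = list(n_mutants = 12))
pipeline_config <- function(seed, out_dir = ".", sim = list(),
                            gate_percentile = 5, gate_threshold = NULL,
                            min_events = 100,
                            band = list(lower = 0.785, upper = 1.274),
                            anchor_strain = "RbsB", wild_type = "RbsB",
                            reference_batch = NULL, digits = 3) {
  if (missing(seed)) abort("`seed` is mandatory.")
  explicit <- any(c("lower", "upper") %in% names(band))
  derived <- "sd_log" %in% names(band)
  if (explicit && derived) {
    abort("Band misconfigured: give explicit bounds or (sd_log, level), not both.")
  }
  if (!explicit && !derived) {
    abort("Band misconfigured: give explicit bounds or (sd_log, level).")
  }
  band_obj <- if (explicit) {
    significance_band(lower = band$lower, upper = band$upper,
                      level = band$level %||% 0.99)
  } else {
    significance_band(sd_log = band$sd_log, level = band$level %||% 0.99)
  }
  structure(
    list(seed = seed, out_dir = out_dir, sim = sim,
         gate_percentile = gate_percentile, gate_threshold = gate_threshold,
         min_events = min_events, band = band_obj, band_spec = band,
         anchor_strain = anchor_strain, wild_type = wild_type,
         reference_batch = reference_batch, digits = digits),
    class = "alascan_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", name, "] ", conditionMessage(e)))
  })
}

#' Run the full pipeline on a simulated library
#'
#' Simulates a complete alanine-scan dataset under the configured seed, then
#' runs every analysis stage and writes all artifacts to `out_dir`:
#' `truth.tsv`, `platemap.tsv`, `spectral_counts.tsv`,
#' `induction_summary.tsv`, `thresholds.json`, `abundance.tsv`,
#' `effects.tsv`, `effect_summary.json`, `annotations.tsv`,
#' `annotations_attr.tsv`, and a `manifest.json` recording the seed, a
#' configuration hash, the package version and a content hash per output.
#' Identical configuration implies byte-identical outputs.
#'
#' @param config An [pipeline_config()] object (or a YAML path).
#' @return Invisibly, a list with the in-memory stage results
#'   (`truth`, `induction`, `thresholds`, `abundance`, `effects`,
#'   `annotations`, `manifest`).
#' @export
#' @examples
#' res <- run_pipeline(pipeline_config(
#'   seed = 1, out_dir = file.path(tempdir(), "demo"),
#'   sim = list(n_mutants = 15, event_count_per_well = 300)))
#' glance(res$effects)
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "alascan_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- modifyList(config$sim, list(seed = config$seed))
  sim <- stage("simulate", {
    simulate_library(do.call(sim_config, sim_args))
  })

  induction <- stage("induction", {
    gated <- gate_events(sim$events, threshold = config$gate_threshold,
                         percentile = config$gate_percentile)
    wells <- well_means(gated, sim$platemap, min_events = config$min_events)
    summaries <- summarize_induction(wells)
    thresholds <- induction_thresholds(summaries)
    list(summaries = classify_induction(summaries, thresholds),
         thresholds = thresholds)
  })

  abundance <- stage("abundance", {
    quantify_abundance(sim$spectral, config$band,
                       anchor_strain = config$anchor_strain,
                       reference_batch = config$reference_batch)
  })

  effects <- stage("categorize", {
    assemble_effect_table(induction$summaries, abundance,
                          wild_type = config$wild_type, band = config$band)
  })

  annotations <- stage("annotate", {
    sequence <- paste(sim$truth$wt_residue, collapse = "")
    meta <- sim$truth %>%
      select("position", "wt_residue") %>%
      left_join(
        effects %>%
          as_tibble() %>%
          left_join(select(sim$truth, "mutant_id", "position"),
                    by = c(strain_id = "mutant_id")) %>%
          select("position", "category", "induction_class"),
        by = "position"
      )
    validate_positions(meta, sequence)
  })

  paths <- c(
    truth = "truth.tsv", platemap = "platemap.tsv",
    spectral = "spectral_counts.tsv", induction = "induction_summary.tsv",
    thresholds = "thresholds.json", abundance = "abundance.tsv",
    effects = "effects.tsv", effect_summary = "effect_summary.json",
    annotations = "annotations.tsv", annotations_attr = "annotations_attr.tsv"
  )
  paths <- setNames(file.path(config$out_dir, paths), names(paths))
  readr::write_tsv(sim$truth, paths[["truth"]])
  write_platemap(sim$platemap, paths[["platemap"]])
  write_spectral_counts(sim$spectral, paths[["spectral"]])
  write_induction(induction$summaries, paths[["induction"]])
  jsonlite::write_json(tidy(induction$thresholds), paths[["thresholds"]],
                       digits = NA)
  write_abundance(abundance, paths[["abundance"]])
  write_effects(effects, paths[["effects"]])
  jsonlite::write_json(glance(effects), paths[["effect_summary"]],
                       digits = NA)
  export_annotations(annotations, paths[["annotations"]], format = "table")
  export_annotations(annotations, paths[["annotations_attr"]],
                     format = "attribute")

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("band", "out_dir"))]),
    package_version = as.character(utils::packageVersion("alascan")),
    outputs = purrr::map(paths, ~ list(
      file = basename(.x),
      hash = rlang::hash(readr::read_file(.x))
    ))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(truth = sim$truth, induction = induction$summaries,
                 thresholds = induction$thresholds, abundance = abundance,
                 effects = effects, annotations = annotations,
                 manifest = manifest))
}
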