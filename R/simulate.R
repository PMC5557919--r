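#' Configuration for synthetic alanine-scan datasets
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' study conditions of the RbsB reference screen: 232 mutants in the
#' reference class proportions, a baseline uninduced reporter mean of 2851
#' fluorescence units with a wild-type fold induction of 8.30, triplicate
#' wells per strain and condition, log-normal event fluorescence, a
#' low-scatter background sub-population, and Poisson spectral counts over
#' two MS batches anchored by the wild-type.
#'
#' @param n_mutants Number of mutants in the library.
#' @param class_proportions Named simplex over the four induction classes
#'   (must sum to 1 within 1e-9).
#' @param baseline_uninduced_mean Wild-type uninduced reporter mean
#'   (arbitrary fluorescence units).
#' @param wild_type_fold Wild-type fold induction.
#' @param event_count_per_well Events recorded per well.
#' @param event_log_sd Log-SD of event fluorescence within a population.
#' @param background_fraction Fraction of events per well that are
#'   low-scatter background particles, in \[0, 1).
#' @param replicates Biological replicate wells per strain and condition
#'   (>= 2 so an SD is computable).
#' @param replicate_log_sd Log-SD of between-replicate well-mean variation.
#' @param mutant_log_sd Log-SD of between-mutant baseline variation.
#' @param ms_depth_mean Expected total identified spectra per MS sample.
#' @param ms_batch_factors Named positive multipliers, one per MS batch.
#' @param wt_target_rate Expected fraction of total spectra that are
#'   exclusive to the wild-type target protein.
#' @param standard_abundance Expected fraction of total spectra exclusive to
#'   the internal standard.
#' @param nb_size Optional negative-binomial size parameter; `NULL` (the
#'   default) keeps counts Poisson.
#' @param scatter_mean,scatter_log_sd Log-normal scatter of intact cells.
#' @param background_scatter_mean,background_scatter_log_sd Log-normal
#'   scatter of background particles (well below the cell population).
#' @param fluorescence_floor Instrument fluorescence floor for background
#'   particles.
#' @param wt_fold_window Wild-type-like mutants keep their planted fold
#'   within this factor of `wild_type_fold`.
#' @param band [significance_band()] used to derive planted categories.
#' @param seed Integer seed; mandatory, all draws flow from it.
#' @return A validated list of class `alascan_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_mutants = 20)
sim_config <- function(n_mutants = 232,
                       class_proportions = c(non_inducible = 0.043,
                                             poorly_inducible = 0.056,
                                             semi_constitutive = 0.070,
                                             wild_type_like = 0.831),
                       baseline_uninduced_mean = 2851,
                       wild_type_fold = 8.30,
                       event_count_per_well = 2000,
                       event_log_sd = 0.4,
                       background_fraction = 0.05,
                       replicates = 3,
                       replicate_log_sd = 0.08,
                       mutant_log_sd = 0.10,
                       ms_depth_mean = 20000,
                       ms_batch_factors = c(b1 = 1, b2 = 1.3),
                       wt_target_rate = 0.05,
                       standard_abundance = 0.04,
                       nb_size = NULL,
                       scatter_mean = 5e4,
                       scatter_log_sd = 0.3,
                       background_scatter_mean = 2e3,
                       background_scatter_log_sd = 0.5,
                       fluorescence_floor = 50,
                       wt_fold_window = 1.5,
                       band = significance_band(upper = 1.274),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in the simulation config.")
  cfg <- as.list(environment())
  if (!setequal(names(class_proportions), induction_levels())) {
    abort("`class_proportions` must be named by the four induction classes.")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1 within 1e-9.")
  }
  if (any(class_proportions < 0)) abort("`class_proportions` must be >= 0.")
  if (replicates < 2) abort("`replicates` must be >= 2 (SD must be computable).")
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must be in [0, 1).")
  }
  stopifnot(n_mutants >= 1, baseline_uninduced_mean > 0, wild_type_fold > 0,
            event_count_per_well >= 1, event_log_sd >= 0,
            ms_depth_mean > 0, all(ms_batch_factors > 0),
            wt_target_rate > 0, standard_abundance > 0)
  structure(cfg, class = "alascan_sim_config")
}

# draw (signaling factor s, abundance multiplier a, fold f, uninduced factor u)
# for one mutant of a given class; the generative model is the
# proportionality assumption itself: induced mean = baseline * fold, with
# fold = wild_type_fold * s * a for induction-relevant classes.
draw_mechanism <- function(class, config) {
  wf <- config$wild_type_fold
  u <- 1
  if (class == "wild_type_like") {
    s <- exp(stats::rnorm(1, 0, 0.05))
    a <- runif(1, 0.95, 1.05)
    f <- wf * s * a
  } else if (class == "non_inducible") {
    f <- runif(1, 0.60, 0.90)
    mech <- sample(c("signaling", "both", "abundance"), 1,
                   prob = c(0.5, 0.3, 0.2))
    if (mech == "signaling") {
      a <- runif(1, 0.95, 1.05); s <- f / (wf * a)
    } else if (mech == "both") {
      a <- runif(1, 0.25, 0.50); s <- f / (wf * a)
    } else {
      s <- runif(1, 0.90, 1.10); a <- f / (wf * s)
    }
  } else if (class == "poorly_inducible") {
    mech <- sample(c("signaling", "both", "abundance"), 1,
                   prob = c(0.4, 0.3, 0.3))
    if (mech == "signaling") {
      f <- runif(1, 1.6, 3.4); a <- runif(1, 0.95, 1.05); s <- f / (wf * a)
    } else if (mech == "both") {
      f <- runif(1, 1.6, 2.6)
      s <- runif(1, f / (wf * 0.55), 0.70)
      a <- f / (wf * s)
    } else {
      f <- runif(1, 1.6, 3.4); s <- runif(1, 0.90, 1.10); a <- f / (wf * s)
    }
  } else { # semi_constitutive: raised uninduced level, maintained fold
    u <- runif(1, 2.7, 3.3)
    f <- runif(1, 3.8, 4.8)
    s <- 1
    a <- if (runif(1) < 0.3) runif(1, 0.30, 0.50) else runif(1, 0.95, 1.05)
  }
  list(s = s, a = a, f = f, u = u)
}

#' Generate the planted per-mutant truth table
#'
#' Draws class counts multinomially from the configured proportions, then,
#' per mutant, a mechanism (signaling factor, abundance multiplier) and the
#' implied fold induction and expected well means. The planted effect
#' category is derived by applying the categorization rules
#' ([categorize_effects()]) to the planted true values, so truth and rules
#' are consistent by construction and downstream recovery measures
#' estimation error only.
#'
#' @param config An [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return Tibble with one row per mutant: `mutant_id`, `position`,
#'   `induction_class_true`, `fold_true`, `signaling_factor_true`,
#'   `abundance_multiplier_true`, `uninduced_mean_true`,
#'   `induced_mean_true`, `category_true`.
#' @export
#' @examples
#' generate_truth(sim_config(seed = 7, n_mutants = 12))
generate_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "alascan_sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  props <- config$class_proportions[induction_levels()]
  counts <- as.vector(rmultinom(1, config$n_mutants, props))
  classes <- sample(rep(induction_levels(), counts))
  mech <- purrr::map(classes, draw_mechanism, config = config)
  mut_noise <- exp(stats::rnorm(config$n_mutants, 0, config$mutant_log_sd))
  uninduced <- config$baseline_uninduced_mean * mut_noise *
    purrr::map_dbl(mech, "u")
  fold <- purrr::map_dbl(mech, "f")
  a <- purrr::map_dbl(mech, "a")
  f_true <- uninduced * fold /
    (config$baseline_uninduced_mean * config$wild_type_fold)
  non_ala <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A")
  truth <- tibble(
    mutant_id = sprintf("M%03d", seq_len(config$n_mutants)),
    position = seq_len(config$n_mutants),
    wt_residue = sample(non_ala, config$n_mutants, replace = TRUE),
    induction_class_true = classes,
    fold_true = fold,
    signaling_factor_true = purrr::map_dbl(mech, "s"),
    abundance_multiplier_true = a,
    uninduced_mean_true = uninduced,
    induced_mean_true = uninduced * fold
  )
  truth %>%
    mutate(
      category_true = as.character(categorize_effects(
        .data$induction_class_true, f_true, a,
        classify_abundance(a, config$band), config$band
      ))
    )
}

#' Simulate the events of one well
#'
#' Event fluorescence is log-normal around the class-determined population
#' mean (`uninduced_mean_true`, times `fold_true` when induced), with a
#' per-well replicate factor. A configured fraction of events are background
#' particles with sub-gate scatter and near-floor fluorescence.
#'
#' @param truth One row of the truth table from [generate_truth()] (or any
#'   list with `uninduced_mean_true` and `fold_true`).
#' @param condition `"uninduced"` or `"induced"`.
#' @param config An [sim_config()] object.
#' @param replicate Replicate index (bookkeeping only).
#' @param well_id Well label.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return Tibble with `well_id`, `event_index`, `scatter`, `fluorescence`.
#' @export
simulate_events <- function(truth, condition, config, replicate = 1,
                            well_id = NULL, seed = NULL) {
  stopifnot(inherits(config, "alascan_sim_config"))
  if (!condition %in% c("uninduced", "induced")) {
    abort("`condition` must be 'uninduced' or 'induced'.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- config$event_count_per_well
  n_bg <- round(n * config$background_fraction)
  n_cell <- n - n_bg
  mu <- truth$uninduced_mean_true *
    (if (condition == "induced") truth$fold_true else 1) *
    exp(stats::rnorm(1, 0, config$replicate_log_sd))
  sdl <- config$event_log_sd
  fl_cells <- rlnorm(n_cell, log(mu) - sdl^2 / 2, sdl)
  sc_cells <- rlnorm(n_cell,
                     log(config$scatter_mean) - config$scatter_log_sd^2 / 2,
                     config$scatter_log_sd)
  fl_bg <- rlnorm(n_bg, log(config$fluorescence_floor), 0.5)
  sc_bg <- rlnorm(n_bg,
                  log(config$background_scatter_mean) -
                    config$background_scatter_log_sd^2 / 2,
                  config$background_scatter_log_sd)
  if (is.null(well_id)) {
    well_id <- paste(truth$mutant_id %||% "well", condition, replicate,
                     sep = "_")
  }
  tibble(
    well_id = well_id,
    event_index = seq_len(n),
    scatter = c(sc_cells, sc_bg),
    fluorescence = c(fl_cells, fl_bg)
  )
}

#' Simulate one spectral-count sample
#'
#' Exclusive target counts are Poisson with rate `abundance multiplier x
#' wild-type target rate x depth x batch factor`; internal-standard counts
#' Poisson at `standard_abundance x depth x batch factor`; total spectra
#' Poisson at `depth x batch factor`, floored at target + standard. An
#' optional negative-binomial switch (`nb_size`) adds overdispersion.
#'
#' @param truth One truth row (needs `abundance_multiplier_true` and
#'   `mutant_id`).
#' @param config An [sim_config()] object.
#' @param batch Batch label, present in `config$ms_batch_factors`.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return One-row tibble: `sample_id`, `strain_id`, `batch`,
#'   `target_count`, `standard_count`, `total_spectra`.
#' @export
simulate_spectral_sample <- function(truth, config, batch, seed = NULL) {
  stopifnot(inherits(config, "alascan_sim_config"))
  if (!batch %in% names(config$ms_batch_factors)) {
    abort(paste0("Batch '", batch, "' not in `ms_batch_factors`."))
  }
  if (!is.null(seed)) set.seed(seed)
  fac <- config$ms_batch_factors[[batch]]
  depth <- config$ms_depth_mean
  draw <- function(mu) {
    if (is.null(config$nb_size)) rpois(1, mu)
    else stats::rnbinom(1, mu = mu, size = config$nb_size)
  }
  target <- draw(truth$abundance_multiplier_true * config$wt_target_rate *
                   depth * fac)
  standard <- draw(config$standard_abundance * depth * fac)
  total <- max(draw(depth * fac), target + standard)
  tibble(
    sample_id = paste0(truth$mutant_id, "_", batch),
    strain_id = truth$mutant_id,
    batch = batch,
    target_count = target,
    standard_count = standard,
    total_spectra = total
  )
}

#' Simulate a complete alanine-scan dataset
#'
#' Generates, under a single seeded stream, the truth table, the plate map,
#' event-level flow data for every strain (mutants plus a wild-type control
#' strain `RbsB`) in both conditions and all replicates, and one spectral
#' sample per mutant with the wild-type measured once in every batch
#' (anchoring). Mutants are assigned to MS batches in alternation.
#'
#' @param config An [sim_config()] object.
#' @return List with tibbles `truth`, `platemap`, `events`, `spectral`.
#' @export
#' @examples
#' sim <- simulate_library(sim_config(seed = 1, n_mutants = 12,
#'                                    event_count_per_well = 200))
#' names(sim)
simulate_library <- function(config) {
  stopifnot(inherits(config, "alascan_sim_config"))
  set.seed(config$seed)
  truth <- generate_truth(config, seed = config$seed)
  wt <- tibble(
    mutant_id = "RbsB", position = NA_integer_,
    induction_class_true = "wild_type_like", fold_true = config$wild_type_fold,
    signaling_factor_true = 1, abundance_multiplier_true = 1,
    uninduced_mean_true = config$baseline_uninduced_mean,
    induced_mean_true = config$baseline_uninduced_mean * config$wild_type_fold,
    category_true = NA_character_
  )
  strains <- bind_rows(truth, wt)
  platemap <- tidyr::crossing(
    strain_id = strains$mutant_id,
    condition = c("uninduced", "induced"),
    replicate = seq_len(config$replicates)
  ) %>%
    arrange(match(.data$strain_id, strains$mutant_id), .data$condition,
            .data$replicate) %>%
    mutate(
      well_id = sprintf("W%04d", row_number()),
      plate_id = sprintf("P%02d", 1 + (row_number() - 1) %/% 96)
    ) %>%
    select("well_id", "strain_id", "condition", "replicate", "plate_id")
  events <- platemap %>%
    left_join(strains, by = c("strain_id" = "mutant_id")) %>%
    purrr::pmap(function(well_id, strain_id, condition, replicate, plate_id,
                         ...) {
      simulate_events(list(mutant_id = strain_id, ...), condition, config,
                      replicate = replicate, well_id = well_id)
    }) %>%
    bind_rows()
  batches <- names(config$ms_batch_factors)
  truth_batch <- rep_len(batches, nrow(truth))
  spectral <- bind_rows(c(
    purrr::map(seq_len(nrow(truth)),
               ~ simulate_spectral_sample(truth[.x, ], config,
                                          truth_batch[[.x]])),
    purrr::map(batches, ~ simulate_spectral_sample(wt, config, .x))
  ))
  list(truth = truth, platemap = platemap, events = events,
       spectral = spectral)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
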