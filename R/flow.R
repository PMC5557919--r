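#' Gate flow-cytometry events on forward scatter
#'
#' Removes background particles (debris, electronic noise) below a scatter
#' cutoff before fluorescence means are taken. The cutoff is either an
#' absolute scatter value (`threshold`) or, by default, a per-well lower
#' percentile of the scatter distribution (`percentile`, default 5), since
#' instrument-specific absolute cutoffs rarely transfer between runs.
#'
#' @param events Data frame of events with columns `well_id`, `scatter`,
#'   `fluorescence` (one or many wells).
#' @param threshold Absolute scatter cutoff; events with `scatter >=
#'   threshold` are kept. Overrides `percentile` when given.
#' @param percentile Per-well lower percentile of scatter to remove, in
#'   \[0, 100).
#' @return The gated events tibble (same columns).
#' @export
#' @examples
#' ev <- tibble::tibble(well_id = "A1", scatter = c(1, 10, 50, 80),
#'                      fluorescence = c(5, 200, 300, 400))
#' gate_events(ev, threshold = 5)
gate_events <- function(events, threshold = NULL, percentile = 5) {
  stopifnot(all(c("well_id", "scatter", "fluorescence") %in% names(events)))
  if (nrow(events) == 0) abort("No events to gate.")
  if (!is.null(threshold)) {
    gated <- dplyr::filter(events, .data$scatter >= .env$threshold)
  } else {
    if (percentile < 0 || percentile >= 100) {
      abort("`percentile` must be in [0, 100).")
    }
    gated <- events %>%
      group_by(.data$well_id) %>%
      filter(.data$scatter >= quantile(.data$scatter, percentile / 100,
                                       names = FALSE)) %>%
      ungroup()
  }
  lost <- setdiff(unique(events$well_id), unique(gated$well_id))
  if (length(lost) > 0) {
    abort(paste0("Gating removed all events in well(s): ",
                 paste(lost, collapse = ", ")))
  }
  as_tibble(gated)
}

#' Per-well mean fluorescence of gated events
#'
#' Computes the arithmetic mean fluorescence and gated event count per well,
#' optionally joining well metadata (strain, condition, replicate, plate)
#' from a plate map. Wells with fewer than `min_events` gated events are
#' flagged (`qc_pass = FALSE`) with a warning and are excluded by
#' [summarize_induction()].
#'
#' @param events Gated events (see [gate_events()]).
#' @param platemap Optional data frame with `well_id`, `strain_id`,
#'   `condition`, `replicate` (and optionally `plate_id`).
#' @param min_events Minimum gated events for a trustworthy mean
#'   (default 100).
#' @return Tibble with `well_id`, `mean_fluorescence`, `n_gated`, `qc_pass`,
#'   plus plate-map columns when supplied.
#' @export
well_means <- function(events, platemap = NULL, min_events = 100) {
  stopifnot(all(c("well_id", "fluorescence") %in% names(events)))
  out <- events %>%
    group_by(.data$well_id) %>%
    summarise(
      mean_fluorescence = mean(.data$fluorescence),
      n_gated = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(qc_pass = .data$n_gated >= .env$min_events)
  if (any(!out$qc_pass)) {
    warn(paste0(
      "Well(s) below the minimum gated-event threshold (", min_events,
      "), flagged and excluded downstream: ",
      paste(out$well_id[!out$qc_pass], collapse = ", ")
    ))
  }
  if (!is.null(platemap)) {
    stopifnot(all(c("well_id", "strain_id", "condition", "replicate")
                  %in% names(platemap)))
    out <- left_join(out, as_tibble(platemap), by = "well_id")
  }
  out
}

#' Summarize replicate wells into per-strain induction statistics
#'
#' Aggregates replicate well means per strain and condition into the
#' per-strain summary used throughout: mean and sample SD (n-1 denominator)
#' over replicate well means for the uninduced and induced condition, and
#' the fold induction, defined exactly as `mean_induced / mean_uninduced`.
#'
#' @param wells Data frame of per-well means with columns `strain_id`,
#'   `condition` (values `"uninduced"`/`"induced"`), `replicate`,
#'   `mean_fluorescence`, and optionally `qc_pass` (flagged wells are
#'   dropped).
#' @return Tibble with one row per strain: `strain_id`, `mean_uninduced`,
#'   `sd_uninduced`, `mean_induced`, `sd_induced`, `fold_induction`,
#'   `n_replicates` (minimum over the two conditions).
#' @export
#' @examples
#' wells <- tidyr::crossing(strain_id = "RbsB", replicate = 1:3,
#'                          condition = c("uninduced", "induced"))
#' wells$mean_fluorescence <- ifelse(wells$condition == "induced", 23663, 2851)
#' summarize_induction(wells)
summarize_induction <- function(wells) {
  needed <- c("strain_id", "condition", "replicate", "mean_fluorescence")
  stopifnot(all(needed %in% names(wells)))
  if ("qc_pass" %in% names(wells)) {
    wells <- filter(wells, .data$qc_pass)
  }
  bad_cond <- setdiff(unique(wells$condition), c("uninduced", "induced"))
  if (length(bad_cond) > 0) {
    abort(paste0("Unknown condition label(s): ", paste(bad_cond, collapse = ", ")))
  }
  per_cond <- wells %>%
    group_by(.data$strain_id, .data$condition) %>%
    summarise(
      m = mean(.data$mean_fluorescence),
      s = sd(.data$mean_fluorescence),
      k = dplyr::n(),
      .groups = "drop"
    )
  missing <- per_cond %>%
    group_by(.data$strain_id) %>%
    summarise(ok = all(c("uninduced", "induced") %in% .data$condition),
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(missing) > 0) {
    abort(paste0("Both conditions required; missing a condition for: ",
                 paste(missing$strain_id, collapse = ", ")))
  }
  if (any(per_cond$k < 2)) {
    bad <- unique(per_cond$strain_id[per_cond$k < 2])
    abort(paste0("At least 2 replicate wells per condition required for: ",
                 paste(bad, collapse = ", ")))
  }
  out <- per_cond %>%
    tidyr::pivot_wider(names_from = "condition", values_from = c("m", "s", "k")) %>%
    dplyr::transmute(
      strain_id = .data$strain_id,
      mean_uninduced = .data$m_uninduced,
      sd_uninduced = .data$s_uninduced,
      mean_induced = .data$m_induced,
      sd_induced = .data$s_induced,
      n_replicates = pmin(.data$k_uninduced, .data$k_induced)
    )
  if (any(out$mean_uninduced == 0)) {
    abort(paste0("Fold induction undefined (zero uninduced mean) for: ",
                 paste(out$strain_id[out$mean_uninduced == 0], collapse = ", ")))
  }
  out %>%
    mutate(fold_induction = .data$mean_induced / .data$mean_uninduced,
           .before = "n_replicates")
}

#' Library-wide classification thresholds
#'
#' The phenotype calls are relative to the whole assayed library (all
#' mutants plus wild-type): a strain is scored against the mean of the
#' per-strain uninduced and induced means, +/- two library SDs. The upper
#' uninduced bound (`mean + 2 SD` of uninduced means) defines elevated
#' background; the lower induced bound (`mean - 2 SD` of induced means)
#' defines impaired induction.
#'
#' Statistics are computed over per-strain means (one value per strain, the
#' wild-type included once), not over individual replicate wells.
#'
#' @param summaries Per-strain summaries from [summarize_induction()].
#' @param min_strains Minimum library size for meaningful thresholds
#'   (default 10).
#' @return An `alascan_thresholds` object; see [tidy.alascan_thresholds()].
#' @export
#' @examples
#' induction_thresholds(summarize_rbsb())
induction_thresholds <- function(summaries, min_strains = 10) {
  stopifnot(all(c("mean_uninduced", "mean_induced") %in% names(summaries)))
  if (nrow(summaries) < min_strains) {
    abort(paste0("At least ", min_strains,
                 " strains are required to compute library thresholds (got ",
                 nrow(summaries), ")."))
  }
  mu_u <- mean(summaries$mean_uninduced)
  sd_u <- sd(summaries$mean_uninduced)
  mu_i <- mean(summaries$mean_induced)
  sd_i <- sd(summaries$mean_induced)
  structure(
    list(
      mean_uninduced_all = mu_u, sd_uninduced_all = sd_u,
      mean_induced_all = mu_i, sd_induced_all = sd_i,
      upper_uninduced = mu_u + 2 * sd_u,
      lower_induced = mu_i - 2 * sd_i,
      n_strains = nrow(summaries)
    ),
    class = "alascan_thresholds"
  )
}

#' @export
print.alascan_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<library induction thresholds> %d strains\n",
           "  uninduced: mean %.0f, SD %.0f -> upper bound %.0f\n",
           "  induced:   mean %.0f, SD %.0f -> lower bound %.0f\n"),
    x$n_strains, x$mean_uninduced_all, x$sd_uninduced_all, x$upper_uninduced,
    x$mean_induced_all, x$sd_induced_all, x$lower_induced
  ))
  invisible(x)
}

#' Tidy and glance methods for library thresholds
#'
#' @param x An `alascan_thresholds` object.
#' @param ... Unused.
#' @return A one-row tibble of the threshold components.
#' @method tidy alascan_thresholds
#' @export
tidy.alascan_thresholds <- function(x, ...) {
  as_tibble(x[c("mean_uninduced_all", "sd_uninduced_all", "mean_induced_all",
                "sd_induced_all", "upper_uninduced", "lower_induced",
                "n_strains")])
}

#' @rdname tidy.alascan_thresholds
#' @method glance alascan_thresholds
#' @export
glance.alascan_thresholds <- function(x, ...) tidy.alascan_thresholds(x)

#' Classify strains into induction phenotype classes
#'
#' Assigns each strain exactly one label by ordered rules:
#'
#' 1. `semi_constitutive`: the uninduced mean minus its SD exceeds the
#'    library upper uninduced bound (elevated background beyond replicate
#'    spread);
#' 2. `non_inducible`: induced mean below the library lower induced bound
#'    and fold induction <= 1;
#' 3. `poorly_inducible`: induced mean below the lower induced bound with
#'    fold induction > 1;
#' 4. `wild_type_like` otherwise.
#'
#' The semi-constitutive rule takes precedence; a semi-constitutive strain
#' whose induced mean is also below the lower bound keeps its label but is
#' flagged in `impaired_secondary`.
#'
#' @param summaries Per-strain summaries from [summarize_induction()].
#' @param thresholds An [induction_thresholds()] object computed from the
#'   same library.
#' @return `summaries` with `induction_class` (factor in class order) and
#'   `impaired_secondary` (logical) added.
#' @export
classify_induction <- function(summaries, thresholds) {
  stopifnot(inherits(thresholds, "alascan_thresholds"))
  impaired <- summaries$mean_induced < thresholds$lower_induced
  semi <- (summaries$mean_uninduced - summaries$sd_uninduced) >
    thresholds$upper_uninduced
  label <- dplyr::case_when(
    semi ~ "semi_constitutive",
    impaired & summaries$fold_induction <= 1 ~ "non_inducible",
    impaired ~ "poorly_inducible",
    TRUE ~ "wild_type_like"
  )
  summaries %>%
    mutate(
      induction_class = factor(label, levels = induction_levels()),
      impaired_secondary = semi & impaired
    )
}

#' Induction summaries of the bundled RbsB reference table
#'
#' Convenience accessor: the reference induction table ([rbsb_induction()])
#' reduced to the columns of [summarize_induction()] output, with the fold
#' recomputed (unrounded) from the printed means.
#'
#' @return A per-strain summary tibble.
#' @export
summarize_rbsb <- function() {
  rbsb_induction() %>%
    dplyr::transmute(
      strain_id = .data$strain_id,
      mean_uninduced = .data$mean_uninduced,
      sd_uninduced = .data$sd_uninduced,
      mean_induced = .data$mean_induced,
      sd_induced = .data$sd_induced,
      fold_induction = .data$mean_induced / .data$mean_uninduced,
      n_replicates = 3L
    )
}
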