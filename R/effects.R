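#' Fluorescence ratio relative to wild-type
#'
#' F = induced reporter mean of the mutant divided by the induced mean of
#' the wild-type, carried unrounded.
#'
#' @param mutant_induced_mean Induced mean(s) of the mutant(s).
#' @param wild_type_induced_mean Induced mean of the wild-type (> 0).
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' fluorescence_ratio(24383, 23663)   # ~1.030
fluorescence_ratio <- function(mutant_induced_mean, wild_type_induced_mean) {
  stopifnot(is.finite(wild_type_induced_mean), wild_type_induced_mean > 0)
  mutant_induced_mean / wild_type_induced_mean
}

#' Assign mechanistic effect categories
#'
#' Combines the induction phenotype, the fluorescence ratio F and the
#' abundance ratio A under the proportionality assumption: a pure abundance
#' defect reduces reporter output in proportion to periplasmic abundance, so
#' F/A near 1 indicates no signaling defect beyond the abundance loss, while
#' F/A clearly below 1 reveals an additional signaling defect. "Clearly
#' below" reuses the abundance band's lower bound as the F/A threshold.
#'
#' Ordered rules:
#'
#' 1. `signaling_and_abundance`: abundance significance `low`, induction
#'    impaired (`non_inducible` or `poorly_inducible`), and F/A below the
#'    band's lower bound;
#' 2. `abundance`: abundance significance `low` (covers semi-constitutive
#'    mutants with low abundance -- induction is maintained);
#' 3. `signaling`: induction impaired with abundance `normal` or `high`;
#' 4. `no_effect` otherwise.
#'
#' @param induction_class Character/factor vector of induction classes.
#' @param f Fluorescence ratios (> 0).
#' @param a Abundance ratios (NC-derived values allowed).
#' @param significance Abundance significance (`low`/`normal`/`high`), e.g.
#'   from [classify_abundance()].
#' @param band An [significance_band()] object.
#' @return Factor of effect categories (`NA` inputs give `unclassified`).
#' @export
#' @examples
#' band <- significance_band(upper = 1.274)
#' categorize_effects("non_inducible", f = 0.073, a = 0.212,
#'                    significance = "low", band = band)
categorize_effects <- function(induction_class, f, a, significance, band) {
  stopifnot(inherits(band, "alascan_band"))
  induction_class <- as.character(induction_class)
  impaired <- induction_class %in% c("non_inducible", "poorly_inducible")
  prop <- f / a
  label <- dplyr::case_when(
    is.na(induction_class) | is.na(a) | is.na(f) | is.na(significance) ~
      "unclassified",
    significance == "low" & impaired & prop < band$lower ~
      "signaling_and_abundance",
    significance == "low" ~ "abundance",
    impaired ~ "signaling",
    TRUE ~ "no_effect"
  )
  factor(label, levels = effect_levels())
}

#' Join induction and abundance streams into the per-mutant effect table
#'
#' One record per mutant with both an induction summary and an abundance
#' result; mutants with induction data only are kept as `unclassified` with
#' a reason. The wild-type strain provides the F and A denominators and is
#' not itself categorized.
#'
#' @param induction Classified induction summaries
#'   ([classify_induction()] output).
#' @param abundance Abundance results ([quantify_abundance()] output).
#' @param wild_type Strain id of the wild-type reference present in both
#'   streams.
#' @param band An [significance_band()] object (also used for the F/A rule).
#' @return A tibble of class `alascan_effects`: `strain_id`,
#'   `induction_class`, `fluorescence_ratio`, `abundance_ratio`, `nc`,
#'   `significance`, `proportionality` (F/A), `category`, `note`.
#' @export
#' @examples
#' band <- significance_band(upper = 1.274)
#' ind <- classify_induction(summarize_rbsb(),
#'                           induction_thresholds(summarize_rbsb()))
#' ab <- quantify_abundance(rbsb_spectral_counts(), band)
#' assemble_effect_table(ind, ab, wild_type = "RbsB", band = band)
assemble_effect_table <- function(induction, abundance, wild_type, band) {
  stopifnot(inherits(band, "alascan_band"),
            "induction_class" %in% names(induction),
            "abundance_ratio" %in% names(abundance))
  if (anyDuplicated(induction$strain_id) > 0) {
    abort("Duplicate strain ids in the induction stream.")
  }
  if (!wild_type %in% induction$strain_id) {
    abort(paste0("Wild-type strain '", wild_type,
                 "' missing from the induction stream."))
  }
  if (!wild_type %in% abundance$strain_id) {
    abort(paste0("Wild-type strain '", wild_type,
                 "' missing from the abundance stream."))
  }
  wt_induced <- induction$mean_induced[induction$strain_id == wild_type]
  ab <- abundance %>%
    distinct(.data$strain_id, .keep_all = TRUE) %>%
    select("strain_id", "abundance_ratio", "nc", "significance")
  out <- induction %>%
    filter(.data$strain_id != .env$wild_type) %>%
    mutate(fluorescence_ratio =
             fluorescence_ratio(.data$mean_induced, wt_induced)) %>%
    left_join(ab, by = "strain_id") %>%
    mutate(
      proportionality = .data$fluorescence_ratio / .data$abundance_ratio,
      category = categorize_effects(.data$induction_class,
                                    .data$fluorescence_ratio,
                                    .data$abundance_ratio,
                                    .data$significance, band),
      note = dplyr::case_when(
        is.na(.data$abundance_ratio) ~ "no abundance data",
        .data$nc ~ "abundance from depth-normalized target only (NC)",
        .data$significance == "low" &
          !(.data$induction_class %in%
              c("non_inducible", "poorly_inducible")) &
          .data$induction_class == "semi_constitutive" ~
          "low abundance with maintained induction",
        .data$significance == "low" &
          .data$proportionality < band$lower &
          .data$category == "signaling_and_abundance" ~
          "fluorescence loss exceeds abundance loss (F/A below band)",
        TRUE ~ ""
      )
    ) %>%
    select("strain_id", "induction_class", "fluorescence_ratio",
           "abundance_ratio", "nc", "significance", "proportionality",
           "category", "note")
  class(out) <- c("alascan_effects", class(out))
  attr(out, "band") <- band
  attr(out, "wild_type") <- wild_type
  out
}

#' Per-category counts of an effect table
#'
#' @param x An `alascan_effects` table from [assemble_effect_table()].
#' @param ... Unused.
#' @return A one-row tibble with the number of mutants per effect category
#'   and the total.
#' @method glance alascan_effects
#' @export
glance.alascan_effects <- function(x, ...) {
  counts <- table(factor(x$category, levels = effect_levels()))
  dplyr::bind_cols(
    as_tibble(as.list(counts)),
    tibble(n_mutants = nrow(x))
  )
}

#' @method tidy alascan_effects
#' @export
#' @rdname glance.alascan_effects
tidy.alascan_effects <- function(x, ...) {
  as_tibble(x)
}
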