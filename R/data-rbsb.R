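#' Reference induction summaries for the RbsB alanine scan
#'
#' Per-strain reporter-induction summaries for the *E. coli* RbsB
#' ribose-binding-protein alanine-scan strains with a significant induction
#' change, plus the wild-type control: triplicate-averaged mean GFP
#' fluorescence (arbitrary units) of gated populations without (`uninduced`)
#' and with (`induced`) 1 mM ribose, the between-replicate sample SDs, and
#' the published two-decimal fold induction. `group` is the published
#' phenotype group; `ms_selected` marks the 25 mutants whose periplasmic
#' abundance was additionally quantified by mass spectrometry (plus
#' wild-type).
#'
#' These values are reference inputs: [summarize_induction()] reproduces the
#' printed folds from the printed means, and [classify_induction()]
#' reproduces the grouping given library-wide thresholds.
#'
#' @return A tibble with columns `strain_id`, `position`, `wt_aa`, `group`,
#'   `mean_uninduced`, `sd_uninduced`, `mean_induced`, `sd_induced`,
#'   `fold_printed`, `ms_selected`.
#' @seealso [rbsb_spectral_counts()], [rbsb_effect_reference()]
#' @export
#' @examples
#' rbsb_induction()
rbsb_induction <- function() {
  tab <- tibble::tribble(
    ~position, ~wt_aa, ~group, ~mean_uninduced, ~sd_uninduced,
    ~mean_induced, ~sd_induced, ~fold_printed, ~ms_selected,
    NA_integer_, NA_character_, "wild_type", 2851, 544, 23663, 2958, 8.30, TRUE,
    6L,   "L", "non_inducible",     2293, 107, 1495,  34,  0.65, TRUE,
    10L,  "T", "non_inducible",     2604, 629, 1884,  454, 0.72, TRUE,
    215L, "D", "non_inducible",     3696, 40,  2816,  25,  0.76, TRUE,
    89L,  "D", "non_inducible",     2416, 503, 1932,  295, 0.80, TRUE,
    29L,  "K", "non_inducible",     2039, 49,  1736,  38,  0.85, TRUE,
    41L,  "N", "non_inducible",     2823, 409, 2459,  84,  0.87, TRUE,
    190L, "N", "non_inducible",     2396, 39,  2179,  92,  0.91, TRUE,
    186L, "V", "non_inducible",     992,  133, 940,   119, 0.95, TRUE,
    196L, "G", "non_inducible",     990,  155, 950,   103, 0.96, TRUE,
    88L,  "L", "non_inducible",     1123, 55,  1103,  28,  0.98, TRUE,
    195L, "L", "poorly_inducible",  1005, 37,  1594,  51,  1.59, TRUE,
    106L, "V", "poorly_inducible",  1107, 262, 1761,  262, 1.59, TRUE,
    264L, "D", "poorly_inducible",  3059, 161, 5726,  456, 1.87, TRUE,
    34L,  "L", "poorly_inducible",  2207, 229, 4432,  115, 2.01, TRUE,
    31L,  "G", "poorly_inducible",  2537, 343, 5761,  165, 2.27, TRUE,
    262L, "P", "poorly_inducible",  1906, 418, 6004,  1649, 3.15, TRUE,
    104L, "D", "poorly_inducible",  1235, 34,  4068,  596, 3.29, FALSE,
    141L, "R", "poorly_inducible",  2123, 494, 7006,  1474, 3.30, TRUE,
    86L,  "I", "poorly_inducible",  2246, 260, 7873,  2393, 3.51, TRUE,
    144L, "G", "poorly_inducible",  2378, 89,  8926,  348, 3.75, TRUE,
    111L, "I", "poorly_inducible",  1963, 170, 8728,  590, 4.45, TRUE,
    237L, "P", "poorly_inducible",  2923, 244, 10267, 2976, 3.51, TRUE,
    233L, "I", "poorly_inducible",  3166, 217, 10555, 2856, 3.33, TRUE,
    105L, "N", "semi_constitutive", 8344, 171, 35539, 219, 4.26, TRUE,
    103L, "S", "semi_constitutive", 7167, 167, 33101, 1963, 4.62, FALSE,
    255L, "E", "semi_constitutive", 6824, 324, 31441, 595, 4.61, FALSE,
    132L, "I", "semi_constitutive", 5741, 731, 24383, 145, 4.25, TRUE,
    80L,  "Q", "semi_constitutive", 5324, 203, 32831, 1549, 6.17, FALSE,
    63L,  "I", "semi_constitutive", 4945, 134, 20414, 660, 4.13, TRUE,
    154L, "F", "semi_constitutive", 4460, 102, 23688, 340, 5.31, FALSE,
    240L, "I", "semi_constitutive", 4314, 395, 23434, 3754, 5.43, FALSE
  )
  dplyr::mutate(
    tab,
    strain_id = ifelse(is.na(.data$position), "RbsB",
                       paste0(.data$wt_aa, .data$position)),
    .before = 1
  )
}

#' Reference spectral-count table for the RbsB alanine scan
#'
#' Label-free quantification of periplasmic RbsB (mutant) abundance for 25
#' selected mutants and wild-type, with the D-galactose-binding periplasmic
#' protein MglB as internal standard. For each MS sample: exclusive spectrum
#' counts of target and standard, the same counts normalized on the total
#' identified spectra per sample (`*_on_total`, as published), the published
#' standard-normalized value (`to_standard_printed`; `NA` for the sample in
#' which MglB was absent, published as NC), and flags. The wild-type strain
#' was measured once in each batch (`RbsB`, `RbsB(2)`) and anchors the
#' batch correction.
#'
#' `standard_low_printed` marks samples published as having an anomalously
#' low internal standard (excluded from the reference average);
#' `target_low_printed` marks samples published as significantly lower in
#' target abundance than expected from the standard's variance.
#'
#' @return A tibble with one row per MS sample.
#' @seealso [quantify_abundance()], [rbsb_induction()]
#' @export
#' @examples
#' rbsb_spectral_counts()
rbsb_spectral_counts <- function() {
  tab <- tibble::tribble(
    ~sample_id, ~strain_id, ~batch, ~target_exclusive, ~standard_exclusive,
    ~target_on_total, ~standard_on_total, ~to_standard_printed,
    ~standard_low_printed, ~target_low_printed,
    "K29A",    "K29",  "b1", 9,   36, 10,  38, 10,  FALSE, TRUE,
    "L34A",    "L34",  "b1", 20,  43, 20,  44, 17,  FALSE, TRUE,
    "G31A",    "G31",  "b1", 18,  40, 20,  44, 17,  FALSE, TRUE,
    "N41A",    "N41",  "b1", 8,   45, 8,   43, 7,   FALSE, TRUE,
    "I63A",    "I63",  "b1", 13,  24, 16,  29, 21,  FALSE, TRUE,
    "I86A",    "I86",  "b1", 18,  45, 17,  43, 15,  FALSE, TRUE,
    "D89A",    "D89",  "b1", 37,  32, 33,  29, 43,  FALSE, FALSE,
    "N105A",   "N105", "b1", 61,  35, 60,  34, 67,  FALSE, FALSE,
    "I111A",   "I111", "b1", 29,  14, 37,  18, 78,  FALSE, FALSE,
    "I132A",   "I132", "b1", 63,  34, 58,  31, 71,  FALSE, FALSE,
    "R141A",   "R141", "b1", 43,  38, 37,  33, 43,  FALSE, FALSE,
    "G144A",   "G144", "b1", 27,  33, 27,  33, 31,  FALSE, FALSE,
    "N190A",   "N190", "b1", 5,   53, 5,   54, 4,   FALSE, TRUE,
    "D215A",   "D215", "b1", 62,  46, 65,  48, 51,  FALSE, FALSE,
    "I233A",   "I233", "b1", 24,  54, 24,  53, 17,  FALSE, TRUE,
    "P237A",   "P237", "b1", 70,  33, 59,  28, 80,  FALSE, FALSE,
    "P262A",   "P262", "b1", 51,  32, 49,  31, 60,  FALSE, FALSE,
    "D264A",   "D264", "b1", 69,  41, 73,  43, 65,  FALSE, FALSE,
    "RbsB",    "RbsB", "b1", 50,  41, 57,  46, 47,  FALSE, FALSE,
    "RbsB(2)", "RbsB", "b2", 115, 46, 134, 54, 95,  FALSE, FALSE,
    "L6A",     "L6",   "b2", 35,  0,  47,  0,  NA,  TRUE,  TRUE,
    "T10A",    "T10",  "b2", 13,  31, 10,  23, 16,  FALSE, TRUE,
    "L88A",    "L88",  "b2", 38,  47, 47,  59, 31,  FALSE, TRUE,
    "V106A",   "V106", "b2", 65,  11, 71,  12, 224, TRUE,  FALSE,
    "V186A",   "V186", "b2", 27,  13, 18,  8,  79,  TRUE,  FALSE,
    "L195A",   "L195", "b2", 31,  24, 31,  24, 49,  FALSE, TRUE,
    "G196A",   "G196", "b2", 36,  18, 45,  22, 76,  FALSE, TRUE
  )
  tab
}

#' Published combined effect assignments for the RbsB alanine scan
#'
#' The published per-mutant synthesis for the 25 MS-quantified mutants:
#' induced reporter fluorescence, the batch-anchored standard-normalized
#' abundance value (`ms_printed`; values that were bracket-annotated as
#' re-anchored to the reference batch carry `ms_bracketed = TRUE`), the
#' fluorescence ratio F (mutant induced mean / wild-type induced mean), the
#' abundance ratio A (normalized mutant count / wild-type count; `NA` where
#' published as NC), and the published effect group. The published 99%
#' abundance null band is 0.785-1.274.
#'
#' @return A tibble with one row per mutant plus the wild-type reference row.
#' @seealso [categorize_effects()], [significance_band()]
#' @export
#' @examples
#' rbsb_effect_reference()
rbsb_effect_reference <- function() {
  tibble::tribble(
    ~strain_id, ~group_published, ~induced_fluorescence, ~ms_printed,
    ~ms_bracketed, ~fluorescence_ratio, ~abundance_ratio, ~abundance_nc,
    "RbsB", "wild_type",               23663, 47,  FALSE, 1,     1,     FALSE,
    "L6",   "signaling_and_abundance", 1495,  23,  TRUE,  0.063, NA,    TRUE,
    "T10",  "signaling_and_abundance", 1884,  8,   TRUE,  0.080, 0.168, FALSE,
    "K29",  "signaling_and_abundance", 1736,  10,  FALSE, 0.073, 0.212, FALSE,
    "G31",  "signaling_and_abundance", 5761,  17,  FALSE, 0.243, 0.367, FALSE,
    "L34",  "signaling_and_abundance", 4432,  17,  FALSE, 0.187, 0.367, FALSE,
    "N41",  "signaling_and_abundance", 2459,  7,   FALSE, 0.104, 0.150, FALSE,
    "L88",  "signaling_and_abundance", 1103,  15,  TRUE,  0.047, 0.323, FALSE,
    "L195", "signaling_and_abundance", 1594,  24,  TRUE,  0.067, 0.512, FALSE,
    "I63",  "abundance",               20414, 21,  FALSE, 0.863, 0.445, FALSE,
    "I86",  "abundance",               7873,  15,  FALSE, 0.333, 0.319, FALSE,
    "N190", "abundance",               2179,  4,   FALSE, 0.092, 0.075, FALSE,
    "I233", "abundance",               10555, 17,  FALSE, 0.446, 0.365, FALSE,
    "V106", "signaling",               1761,  111, TRUE,  0.074, 2.36,  FALSE,
    "P262", "signaling",               6004,  60,  FALSE, 0.254, 1.276, FALSE,
    "G196", "signaling",               950,   38,  TRUE,  0.040, 0.800, FALSE,
    "V186", "signaling",               940,   39,  TRUE,  0.040, 0.831, FALSE,
    "D264", "signaling",               5726,  65,  FALSE, 0.242, 1.370, FALSE,
    "D215", "signaling",               2816,  51,  FALSE, 0.119, 1.093, FALSE,
    "G144", "signaling",               8926,  31,  FALSE, 0.377, 0.660, FALSE,
    "R141", "signaling",               7006,  43,  FALSE, 0.296, 0.905, FALSE,
    "I111", "signaling",               8728,  78,  FALSE, 0.369, 1.659, FALSE,
    "D89",  "signaling",               1932,  43,  FALSE, 0.082, 0.918, FALSE,
    "P237", "signaling",               10267, 80,  FALSE, 0.434, 1.701, FALSE,
    "I132", "no_effect",               24383, 71,  FALSE, 1.030, 1.510, FALSE,
    "N105", "no_effect",               35539, 67,  FALSE, 1.502, 1.424, FALSE
  )
}
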