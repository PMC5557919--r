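#' Normalize exclusive spectrum counts on total spectra
#'
#' Rescales each sample's exclusive counts (target protein and internal
#' standard) to a common sequencing depth, `count * (T_bar / T_sample)`,
#' where `T_bar` is the mean `total_spectra` across the sample set. Any
#' common constant would yield identical downstream ratios; the mean keeps
#' the values on the scale of the raw counts.
#'
#' @param samples Data frame with `target_count`, `standard_count`,
#'   `total_spectra` (> 0).
#' @return `samples` with `target_on_total` and `standard_on_total` added.
#' @export
#' @examples
#' normalize_on_total(tibble::tibble(
#'   sample_id = c("a", "b"), target_count = c(10, 10),
#'   standard_count = c(4, 4), total_spectra = c(100, 200)))
normalize_on_total <- function(samples) {
  needed <- c("target_count", "standard_count", "total_spectra")
  stopifnot(all(needed %in% names(samples)))
  if (nrow(samples) == 0) abort("Empty sample set.")
  if (any(samples$total_spectra <= 0)) {
    abort("All `total_spectra` must be > 0.")
  }
  t_bar <- mean(samples$total_spectra)
  samples %>%
    mutate(
      target_on_total = .data$target_count * t_bar / .data$total_spectra,
      standard_on_total = .data$standard_count * t_bar / .data$total_spectra
    ) %>%
    as_tibble()
}

#' Flag samples whose internal standard is anomalously low
#'
#' The internal standard is only a valid normalizer where its own abundance
#' is unperturbed. A sample is flagged when its depth-normalized standard
#' value falls strictly below 50% of the median across samples; zero values
#' are always flagged. Flagged samples are excluded from the reference
#' average ([reference_average()]) but still receive standard-normalized
#' values.
#'
#' @param standard_on_total Numeric vector of depth-normalized internal
#'   standard values, one per sample (>= 5 samples).
#' @return Logical vector of flags.
#' @export
#' @examples
#' flag_standard_outliers(c(38, 44, 43, 29, 43, 0, 12, 8, 34))
flag_standard_outliers <- function(standard_on_total) {
  if (length(standard_on_total) < 5) {
    abort("At least 5 samples are required to flag internal-standard outliers.")
  }
  med <- median(standard_on_total)
  standard_on_total < 0.5 * med | standard_on_total == 0
}

#' Reference average of the internal standard
#'
#' Arithmetic mean of the depth-normalized internal-standard values over
#' unflagged samples; the denominator scale of [normalize_to_standard()].
#'
#' @param standard_on_total Numeric vector of depth-normalized standard
#'   values.
#' @param flags Logical vector from [flag_standard_outliers()].
#' @return Scalar reference average.
#' @export
reference_average <- function(standard_on_total, flags = NULL) {
  if (is.null(flags)) flags <- rep(FALSE, length(standard_on_total))
  stopifnot(length(flags) == length(standard_on_total))
  keep <- standard_on_total[!flags]
  if (length(keep) == 0) abort("All samples flagged; no reference average.")
  mean(keep)
}

#' Normalize target values to the internal standard
#'
#' `target_on_total * reference / standard_on_total`: expresses the target
#' on the scale it would have if the sample's internal standard sat exactly
#' at the reference average. Samples in which the standard is absent
#' (`standard_on_total = 0`) cannot be corrected and return `NA` (reported
#' downstream as NC, "no correction").
#'
#' @param target_on_total,standard_on_total Depth-normalized values.
#' @param reference Scalar from [reference_average()] (> 0).
#' @return Numeric vector (`NA` where the standard is absent).
#' @export
#' @examples
#' normalize_to_standard(10, 38, 37.67)   # ~9.91
normalize_to_standard <- function(target_on_total, standard_on_total,
                                  reference) {
  stopifnot(reference > 0)
  ifelse(standard_on_total == 0, NA_real_,
         target_on_total * reference / standard_on_total)
}

#' Anchor measurement batches on a strain measured in every batch
#'
#' MS batches acquired on different occasions sit on different effective
#' scales. With one anchor strain (normally the wild-type) measured within
#' each batch, every value is rescaled by `anchor(reference_batch) /
#' anchor(batch)`, leaving the reference batch unchanged. Samples without a
#' standard-normalized value (NC) are corrected on their depth-normalized
#' target value instead, and keep their NC marker.
#'
#' @param df Data frame with columns `batch`, the value column, and, for NC
#'   handling, `target_on_total`; plus `strain_id` if anchors are derived
#'   from the data.
#' @param value Name of the column holding the values to correct (default
#'   `"to_standard"`).
#' @param anchors Named numeric vector `batch -> anchor value`. When `NULL`,
#'   derived from `df` as the `value` of the `anchor_strain` sample in each
#'   batch.
#' @param anchor_strain Strain id anchoring each batch (used when `anchors`
#'   is `NULL`).
#' @param reference_batch Batch left unchanged; defaults to the first batch
#'   appearing in `df`.
#' @return `df` with `batch_corrected` (and `nc` if `target_on_total`
#'   fallback was used) added.
#' @export
#' @examples
#' df <- tibble::tibble(sample_id = c("wt", "m"), batch = c("b1", "b2"),
#'                      to_standard = c(47, 16), target_on_total = c(57, 10))
#' batch_correct(df, anchors = c(b1 = 47, b2 = 95), reference_batch = "b1")
batch_correct <- function(df, value = "to_standard", anchors = NULL,
                          anchor_strain = NULL, reference_batch = NULL) {
  stopifnot("batch" %in% names(df), value %in% names(df))
  batches <- unique(df$batch)
  if (is.null(reference_batch)) reference_batch <- batches[[1]]
  if (is.null(anchors)) {
    if (is.null(anchor_strain)) {
      abort("Supply `anchors` or `anchor_strain`.")
    }
    anchor_rows <- filter(df, .data$strain_id == .env$anchor_strain)
    if (anyDuplicated(anchor_rows$batch) > 0) {
      abort("More than one anchor sample in a batch; anchors must be unique.")
    }
    anchors <- setNames(anchor_rows[[value]], anchor_rows$batch)
  }
  missing <- setdiff(batches, names(anchors))
  if (length(missing) > 0) {
    abort(paste0("No anchor value for batch(es): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(anchors[batches])) || any(anchors[batches] <= 0)) {
    abort("Anchor values must be finite and > 0 in every batch.")
  }
  ratio <- unname(anchors[[reference_batch]] / anchors[df$batch])
  vals <- df[[value]]
  nc <- is.na(vals)
  if (any(nc)) {
    if (!"target_on_total" %in% names(df)) {
      abort("NC samples present but no `target_on_total` column for fallback.")
    }
    vals[nc] <- df$target_on_total[nc]
  }
  df %>% mutate(nc = nc, batch_corrected = vals * ratio)
}

#' Abundance ratio relative to wild-type
#'
#' @param corrected Batch-corrected normalized value(s).
#' @param wild_type_value The wild-type's corrected value (> 0).
#' @return `corrected / wild_type_value`.
#' @export
abundance_ratio <- function(corrected, wild_type_value) {
  stopifnot(is.finite(wild_type_value), wild_type_value > 0)
  corrected / wild_type_value
}

#' Full spectral-count abundance chain
#'
#' Runs the complete normalization chain on a spectral-count table:
#' depth normalization on total spectra, internal-standard outlier
#' flagging, reference averaging, standard normalization (NC where the
#' standard is absent), batch anchoring on the wild-type strain, abundance
#' ratios against the reference-batch wild-type, and significance calls
#' against the band.
#'
#' Input starts either from raw counts (`target_count`, `standard_count`,
#' `total_spectra`) or, when depth-normalized values are already available
#' (e.g. a published table), from `target_on_total`/`standard_on_total`
#' directly.
#'
#' @param samples Data frame with `sample_id`, `strain_id`, `batch` and
#'   count or on-total columns (see Details).
#' @param band An [significance_band()] object.
#' @param anchor_strain Strain anchoring the batches and serving as the
#'   ratio denominator (default `"RbsB"`).
#' @param reference_batch Batch defining the common scale; defaults to the
#'   batch of the first anchor sample in the table.
#' @return Tibble with per-sample `target_on_total`, `standard_on_total`,
#'   `standard_outlier`, `to_standard`, `nc`, `batch_corrected`,
#'   `abundance_ratio`, `significance`.
#' @export
#' @examples
#' band <- significance_band(upper = 1.274)
#' quantify_abundance(rbsb_spectral_counts(), band)
quantify_abundance <- function(samples, band, anchor_strain = "RbsB",
                               reference_batch = NULL) {
  stopifnot(inherits(band, "alascan_band"),
            all(c("sample_id", "strain_id", "batch") %in% names(samples)))
  if (anyDuplicated(samples$sample_id) > 0) {
    abort("Duplicate `sample_id` values in the spectral-count table.")
  }
  if (!all(c("target_on_total", "standard_on_total") %in% names(samples))) {
    samples <- normalize_on_total(samples)
  }
  flags <- flag_standard_outliers(samples$standard_on_total)
  ref <- reference_average(samples$standard_on_total, flags)
  out <- samples %>%
    mutate(
      standard_outlier = flags,
      to_standard = normalize_to_standard(.data$target_on_total,
                                          .data$standard_on_total, ref)
    )
  anchor_rows <- filter(out, .data$strain_id == .env$anchor_strain)
  if (nrow(anchor_rows) == 0) {
    abort(paste0("Anchor strain '", anchor_strain,
                 "' not present in the sample table."))
  }
  if (is.null(reference_batch)) reference_batch <- anchor_rows$batch[[1]]
  out <- batch_correct(out, value = "to_standard",
                       anchor_strain = anchor_strain,
                       reference_batch = reference_batch)
  wt_value <- out$batch_corrected[out$strain_id == anchor_strain &
                                    out$batch == reference_batch]
  out %>%
    mutate(
      abundance_ratio = abundance_ratio(.data$batch_corrected, wt_value),
      significance = classify_abundance(.data$abundance_ratio, band),
      reference_average = ref
    )
}
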