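# File conventions shared by every stage: UTF-8, tab-separated, header row,
# '.' decimal separator, no thousands separators; the no-correction marker is
# written as the literal string NC. readr handles optional gzip (.gz paths)
# transparently.

#' Write and read event tables
#'
#' Events are stored one tabular file per well
#' (`events_<well_id>.tsv[.gz]`, columns `event_index`, `scatter`,
#' `fluorescence`); the well identity lives in the file name and is restored
#' on read.
#'
#' @param events Event tibble with `well_id`, `event_index`, `scatter`,
#'   `fluorescence` (one or many wells).
#' @param dir Directory for the per-well files (created if needed).
#' @param gzip Compress the files.
#' @return `write_events()`: the written paths, invisibly. `read_events()`:
#'   the combined events tibble.
#' @export
write_events <- function(events, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".tsv.gz" else ".tsv"
  paths <- purrr::map_chr(
    split(events, events$well_id),
    function(chunk) {
      path <- file.path(dir, paste0("events_", chunk$well_id[[1]], ext))
      readr::write_tsv(select(chunk, -"well_id"), path)
      path
    }
  )
  invisible(unname(paths))
}

#' @rdname write_events
#' @export
read_events <- function(dir) {
  paths <- list.files(dir, pattern = "^events_.*\\.tsv(\\.gz)?$",
                      full.names = TRUE)
  if (length(paths) == 0) abort(paste0("No event files found in ", dir))
  purrr::map(paths, function(path) {
    well <- sub("^events_(.*)\\.tsv(\\.gz)?$", "\\1", basename(path))
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(event_index = "i",
                                            .default = "d")) %>%
      mutate(well_id = well, .before = 1)
  }) %>%
    bind_rows()
}

#' Write and read plate maps
#'
#' @param platemap Tibble with `well_id`, `strain_id`, `condition`,
#'   `replicate`, `plate_id`.
#' @param path Output/input path (TSV).
#' @return The path (write) or the tibble (read).
#' @export
write_platemap <- function(platemap, path) {
  readr::write_tsv(platemap, path)
  invisible(path)
}

#' @rdname write_platemap
#' @export
read_platemap <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(replicate = "i", .default = "c"))
}

#' Write and read spectral-count tables
#'
#' @param spectral Tibble with `sample_id`, `strain_id`, `batch`,
#'   `target_count`, `standard_count`, `total_spectra`.
#' @param path Output/input path (TSV).
#' @return The path (write) or the tibble (read).
#' @export
write_spectral_counts <- function(spectral, path) {
  readr::write_tsv(spectral, path)
  invisible(path)
}

#' @rdname write_spectral_counts
#' @export
read_spectral_counts <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", strain_id = "c", batch = "c",
                            .default = "d")
  )
}

#' Write and read abundance tables (NC-aware)
#'
#' Standard-normalization values that are undefined because the internal
#' standard was absent are written as the literal `NC` and restored to `NA`
#' with `nc = TRUE` on read.
#'
#' @param abundance Output of [quantify_abundance()].
#' @param path Output/input path (TSV).
#' @return The path (write) or the tibble (read).
#' @export
write_abundance <- function(abundance, path) {
  out <- abundance %>%
    mutate(to_standard = ifelse(.data$nc, "NC",
                                format(.data$to_standard, digits = 15,
                                       trim = TRUE)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE, na = c("", "NA"),
    col_types = readr::cols(sample_id = "c", strain_id = "c", batch = "c",
                            to_standard = "c", significance = "c",
                            standard_outlier = "l", nc = "l",
                            target_on_total = "d", standard_on_total = "d",
                            batch_corrected = "d", abundance_ratio = "d",
                            .default = readr::col_guess())
  ) %>%
    mutate(to_standard = ifelse(.data$to_standard == "NC", NA_real_,
                                suppressWarnings(as.numeric(.data$to_standard))))
}

#' Write and read per-strain induction summary tables
#'
#' @param summaries Output of [summarize_induction()] or
#'   [classify_induction()].
#' @param path Output/input path (TSV).
#' @return The path (write) or the tibble (read).
#' @export
write_induction <- function(summaries, path) {
  readr::write_tsv(summaries, path)
  invisible(path)
}

#' @rdname write_induction
#' @export
read_induction <- function(path) {
  out <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(strain_id = "c", induction_class = "c",
                            impaired_secondary = "l", n_replicates = "i",
                            .default = "d")
  )
  if ("induction_class" %in% names(out)) {
    out$induction_class <- factor(out$induction_class,
                                  levels = induction_levels())
  }
  out
}

#' Write and read effect tables
#'
#' @param effects Output of [assemble_effect_table()].
#' @param path Output/input path (TSV).
#' @return The path (write) or the tibble (read).
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(as_tibble(effects), path)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  out <- readr::read_tsv(
    path, show_col_types = FALSE, na = c("", "NA"),
    col_types = readr::cols(strain_id = "c", induction_class = "c",
                            significance = "c", category = "c", note = "c",
                            nc = "l", .default = "d")
  )
  out$induction_class <- factor(out$induction_class,
                                levels = induction_levels())
  out$category <- factor(out$category, levels = effect_levels())
  out$note[is.na(out$note)] <- ""
  out
}
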