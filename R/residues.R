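#' Validate mutant positions against the mature wild-type sequence
#'
#' Book-keeps the scan on mature-protein, 1-based numbering (first residue
#' of the mature chain = 1). Every mutant's claimed wild-type residue must
#' match the supplied sequence at its position; native alanines are never
#' mutagenized and are marked `native_alanine`; positions for which no
#' substitution could be obtained are marked `not_obtained`; remaining
#' positions without a mutant are `untested`.
#'
#' @param metadata Data frame with `position` (integer >= 1) and
#'   `wt_residue` (single-letter code); optional extra columns (e.g.
#'   `induction_class`, `category`) are carried through.
#' @param sequence Mature protein sequence as a single character string of
#'   one-letter codes (e.g. from [read_protein_fasta()]). Taken as ground
#'   truth.
#' @param not_obtained Integer positions attempted but never recovered.
#' @return Per-residue tibble covering positions `1..nchar(sequence)`:
#'   `position`, `wt_residue`, `status` in `{tested, native_alanine,
#'   not_obtained, untested}`, plus carried metadata columns.
#' @export
#' @examples
#' meta <- tibble::tibble(position = 2L, wt_residue = "D")
#' validate_positions(meta, "KDAGT", not_obtained = 4L)
validate_positions <- function(metadata, sequence, not_obtained = integer(0)) {
  stopifnot(all(c("position", "wt_residue") %in% names(metadata)))
  residues <- strsplit(toupper(sequence), "")[[1]]
  len <- length(residues)
  if (nrow(metadata) > 0) {
    if (any(metadata$position < 1) || any(metadata$position > len)) {
      abort(paste0("Mutant position outside the mature sequence (length ",
                   len, ")."))
    }
    if (anyDuplicated(metadata$position) > 0) {
      abort("Duplicate mutant positions in the metadata.")
    }
    claimed <- toupper(metadata$wt_residue)
    actual <- residues[metadata$position]
    bad <- which(claimed != actual)
    if (length(bad) > 0) {
      abort(paste0(
        "Wild-type residue mismatch at position(s): ",
        paste0(metadata$position[bad], " (claimed ", claimed[bad],
               ", sequence has ", actual[bad], ")", collapse = "; ")
      ))
    }
    if (any(claimed == "A")) {
      abort(paste0("Native alanine position(s) cannot be mutagenized: ",
                   paste(metadata$position[claimed == "A"], collapse = ", ")))
    }
  }
  out <- tibble(position = seq_len(len), wt_residue = residues) %>%
    mutate(status = dplyr::case_when(
      .data$position %in% metadata$position ~ "tested",
      .data$position %in% not_obtained ~ "not_obtained",
      .data$wt_residue == "A" ~ "native_alanine",
      TRUE ~ "untested"
    ))
  extra <- setdiff(names(metadata), c("position", "wt_residue"))
  if (length(extra) > 0) {
    out <- left_join(out, select(metadata, "position", dplyr::all_of(extra)),
                     by = "position")
  }
  out
}

#' Export per-residue annotations
#'
#' Writes either the full annotation table (TSV) or a generic per-residue
#' attribute file (`position<TAB>code`, one line per residue) consumable by
#' molecular structure viewers. An explicit `offset` maps mature-protein
#' numbering onto a crystal-structure chain numbering (added to every
#' position); offsets are never inferred.
#'
#' @param annotations Output of [validate_positions()], optionally with a
#'   `category` column used as the attribute code.
#' @param path Output file path.
#' @param format `"table"` or `"attribute"`.
#' @param offset Integer added to positions on export (default 0).
#' @return `path`, invisibly.
#' @export
export_annotations <- function(annotations, path,
                               format = c("table", "attribute"),
                               offset = 0L) {
  format <- match.arg(format)
  out <- mutate(annotations, position = .data$position + as.integer(offset))
  if (format == "table") {
    readr::write_tsv(out, path)
  } else {
    code <- if ("category" %in% names(out)) {
      dplyr::coalesce(as.character(out$category), out$status)
    } else {
      out$status
    }
    readr::write_tsv(tibble(position = out$position, code = code), path,
                     col_names = FALSE)
  }
  invisible(path)
}

#' Read an annotation table written by [export_annotations()]
#'
#' @param path TSV path (format `"table"`).
#' @return The annotation tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(position = "i", wt_residue = "c",
                                          status = "c", .default = "c"))
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path FASTA path; the first record is used.
#' @return The sequence as a single upper-case character string.
#' @export
read_protein_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = TRUE)
  if (length(seqs) == 0) abort("No sequence records in FASTA file.")
  toupper(as.character(seqs[[1]]))
}
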