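# Shared fixtures, all built in code.

# printed-table comparisons use round-half-away-from-zero
rha <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + 0.5 * sign(x)) / m
}

published_band <- function() significance_band(lower = 0.785, upper = 1.274)

# reference induction summaries carrying the published phenotype groups as
# induction classes (the published groups come from the full 233-strain
# library's thresholds, which the published defect subset alone cannot
# reproduce)
published_induction <- function() {
  groups <- rbsb_induction()[, c("strain_id", "group")]
  out <- merge(summarize_rbsb(), groups, by = "strain_id", sort = FALSE)
  out$induction_class <- factor(
    ifelse(out$group == "wild_type", "wild_type_like", out$group),
    levels = alascan:::induction_levels()
  )
  tibble::as_tibble(out[, setdiff(names(out), "group")])
}

# small, fast simulation configuration for structural tests
tiny_config <- function(seed = 11, n_mutants = 12,
                        event_count_per_well = 200, ...) {
  sim_config(seed = seed, n_mutants = n_mutants,
             event_count_per_well = event_count_per_well, ...)
}

# Synthetic stand-in for the mature 272-residue wild-type sequence (the real
# annotated sequence is not bundled). Consistent with every published
# position/residue pair, the K1/L272 endpoints, the three unobtainable
# positions (135T, 136S, 145F) and exactly 37 native alanines.
synthetic_rbsb_sequence <- function() {
  res <- rep("G", 272)
  known <- rbsb_induction()
  known <- known[!is.na(known$position), ]
  res[known$position] <- known$wt_aa
  res[1] <- "K"; res[272] <- "L"
  res[135] <- "T"; res[136] <- "S"; res[145] <- "F"
  free <- setdiff(seq_len(272),
                  c(known$position, 1, 272, 135, 136, 145))
  res[free[seq_len(37)]] <- "A"
  paste(res, collapse = "")
}

# metadata for every testable (non-alanine, obtainable) position of the
# synthetic sequence: 272 - 37 Ala - 3 not obtained = 232 mutants
synthetic_rbsb_metadata <- function(sequence = synthetic_rbsb_sequence()) {
  res <- strsplit(sequence, "")[[1]]
  pos <- setdiff(which(res != "A"), c(135, 136, 145))
  tibble::tibble(position = pos, wt_residue = res[pos])
}
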