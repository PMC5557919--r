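Package: alascan
Title: Effect Classification for Alanine-Scanning Reporter and Abundance Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for alanine-scanning mutant libraries of
    periplasmic binding proteins assayed with a fluorescent reporter signaling
    chain and label-free quantitative mass spectrometry. Turns event-level
    flow-cytometry measurements into per-strain induction summaries and
    classifies each mutant as non-inducible, poorly inducible,
    semi-constitutive or wild-type-like from library-wide mean +/- 2 SD
    thresholds; normalizes exclusive spectral counts on total spectra and to an
    internal-standard protein with outlier exclusion and wild-type batch
    anchoring; and combines reporter and abundance ratios under a
    proportionality assumption into four mechanistic effect categories
    (signaling defect, abundance defect, both, or no effect). Includes a
    seeded synthetic-data generator with planted effect classes, residue-level
    annotation export for structure viewers, and tidy tabular interfaces
    throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
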