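test_that("on-total normalization rescales to the mean depth", {
  s <- tibble::tibble(sample_id = c("a", "b"), target_count = c(10, 10),
                      standard_count = c(4, 8), total_spectra = c(100, 200))
  out <- normalize_on_total(s)
  expect_equal(out$target_on_total, c(15, 7.5))
  expect_equal(out$standard_on_total, c(6, 6))

  same <- dplyr::mutate(s, total_spectra = 150)
  expect_equal(normalize_on_total(same)$target_on_total, same$target_count)

  doubled <- dplyr::mutate(s, total_spectra = total_spectra * 2)
  expect_equal(normalize_on_total(doubled)$target_on_total,
               out$target_on_total)

  expect_error(normalize_on_total(s[0, ]), "Empty")
  expect_error(normalize_on_total(dplyr::mutate(s, total_spectra = 0)), "> 0")
})

test_that("internal-standard outlier rule isolates the published exclusions", {
  mglb <- rbsb_spectral_counts()$standard_on_total
  flags <- flag_standard_outliers(mglb)
  expect_equal(sort(mglb[flags]), c(0, 8, 12))
  expect_equal(sum(flags), 3)
  # lowest retained value survives
  expect_false(flags[which(mglb == 18)])

  expect_equal(flag_standard_outliers(rep(5, 6)), rep(FALSE, 6))
  # boundary: exactly 50% of the median is not flagged (strict inequality)
  x <- c(10, 10, 10, 10, 5)
  expect_false(flag_standard_outliers(x)[5])
  expect_error(flag_standard_outliers(c(1, 2, 3)), "At least 5")
})

test_that("the reference average is the mean of unflagged standards", {
  mglb <- rbsb_spectral_counts()$standard_on_total
  flags <- flag_standard_outliers(mglb)
  expect_equal(reference_average(mglb, flags), 904 / 24)
  expect_equal(reference_average(7, FALSE), 7)
  expect_equal(reference_average(c(30, 40), c(FALSE, FALSE)), 35)
  expect_error(reference_average(c(1, 2), c(TRUE, TRUE)), "All samples")
})

test_that("standard normalization matches worked examples and marks NC", {
  expect_equal(normalize_to_standard(10, 38, 904 / 24), 10 * (904 / 24) / 38)
  expect_equal(rha(normalize_to_standard(10, 38, 37.67)), 10)
  expect_equal(normalize_to_standard(12, 904 / 24, 904 / 24), 12)
  expect_true(is.na(normalize_to_standard(47, 0, 37.67)))
})

test_that("batch anchoring reproduces the published bracket values", {
  second <- tibble::tibble(
    strain_id = c("RbsB", "L6", "T10", "L88", "V106", "V186", "L195", "G196"),
    batch = c("b1", rep("b2", 7)),
    to_standard = c(47, NA, 16, 31, 224, 79, 49, 76),
    target_on_total = c(57, 47, 10, 47, 71, 18, 31, 45)
  )
  out <- batch_correct(second, anchors = c(b1 = 47, b2 = 95),
                       reference_batch = "b1")
  got <- setNames(rha(out$batch_corrected), out$strain_id)
  expect_equal(got[-1], c(L6 = 23, T10 = 8, L88 = 15, V106 = 111,
                          V186 = 39, L195 = 24, G196 = 38))
  expect_equal(got[["RbsB"]], 47)          # reference batch unchanged
  expect_true(out$nc[out$strain_id == "L6"])
  expect_false(any(out$nc[out$strain_id != "L6"]))

  ident <- batch_correct(second, anchors = c(b1 = 47, b2 = 47),
                         reference_batch = "b1")
  expect_equal(ident$batch_corrected[!ident$nc],
               second$to_standard[!is.na(second$to_standard)])

  expect_error(batch_correct(second, anchors = c(b1 = 47),
                             reference_batch = "b1"), "b2")
})

test_that("abundance ratios match the published worked examples", {
  expect_equal(rha(abundance_ratio(10, 47), 3), 0.213)
  expect_equal(abundance_ratio(47, 47), 1)
  expect_equal(rha(abundance_ratio(67, 47), 3), 1.426)
  expect_error(abundance_ratio(10, 0))
})

test_that("band construction is reciprocal-symmetric in both modes", {
  pub <- significance_band(lower = 0.785, upper = 1.274)
  expect_lt(abs(pub$lower - 1 / pub$upper), 1e-3)
  expect_equal(significance_band(upper = 1.274)$lower, 1 / 1.274)

  for (s in c(0, 0.05, 0.094, 0.3)) {
    for (lev in c(0.9, 0.95, 0.99)) {
      b <- significance_band(sd_log = s, level = lev)
      expect_lt(abs(b$lower * b$upper - 1), 1e-9)
    }
  }
  b0 <- significance_band(sd_log = 0)
  expect_equal(c(b0$lower, b0$upper), c(1, 1))
  expect_equal(classify_abundance(c(0.99, 1.01), b0), c("low", "high"))

  expect_error(significance_band(lower = 0.5, upper = 1.274), "reciprocal")
  expect_error(significance_band(lower = 0.785, sd_log = 0.1), "not both")
  expect_error(significance_band(), "explicit bounds")
})

test_that("abundance classification respects the band bounds", {
  band <- published_band()
  expect_equal(classify_abundance(c(0.660, 0.800, 1.0, 1.274, 1.276, NA),
                                  band),
               c("low", "normal", "normal", "normal", "high", NA))
})

test_that("the F-test mode agrees with the band in calibration", {
  out <- abundance_f_test(c(1, 0.5), sd_log = 0.094, df = 23)
  expect_equal(out$p_value[1], 1)
  expect_lt(out$p_value[2], 0.05)
})

test_that("the full chain is invariant to depth and standard rescaling", {
  cfg <- sim_config(seed = 31, n_mutants = 20)
  sim <- simulate_library(cfg)
  band <- published_band()
  base <- quantify_abundance(sim$spectral, band)

  deeper <- dplyr::mutate(sim$spectral, total_spectra = total_spectra * 7)
  out <- quantify_abundance(deeper, band)
  expect_equal(out$abundance_ratio, base$abundance_ratio)
  expect_equal(out$to_standard, base$to_standard)

  scaled_std <- dplyr::mutate(sim$spectral,
                              standard_count = standard_count * 3)
  out2 <- quantify_abundance(scaled_std, band)
  expect_equal(out2$to_standard, base$to_standard)
})

test_that("planted abundance multipliers are recovered from Poisson counts", {
  cfg <- sim_config(seed = 37, n_mutants = 1)
  multipliers <- c(0.1, 0.5, 1, 2)
  truth <- generate_truth(cfg)[rep(1, 40 * length(multipliers)), ]
  truth$abundance_multiplier_true <- rep(multipliers, each = 40)
  truth$mutant_id <- sprintf("M%03d", seq_len(nrow(truth)))
  set.seed(41)
  samples <- dplyr::bind_rows(c(
    purrr::map(seq_len(nrow(truth)),
               ~ simulate_spectral_sample(truth[.x, ], cfg, "b1")),
    list(simulate_spectral_sample(
      list(mutant_id = "RbsB", abundance_multiplier_true = 1), cfg, "b1"))
  ))
  out <- quantify_abundance(samples, published_band())
  est <- out$abundance_ratio[match(truth$mutant_id, out$strain_id)]
  for (m in multipliers) {
    med <- median(est[truth$abundance_multiplier_true == m])
    expect_lt(abs(med / m - 1), 0.15)
  }
})

test_that("duplicate samples and missing anchors are rejected", {
  s <- rbsb_spectral_counts()
  expect_error(quantify_abundance(dplyr::bind_rows(s, s[1, ]),
                                  published_band()), "Duplicate")
  expect_error(quantify_abundance(s, published_band(),
                                  anchor_strain = "nope"), "nope")
})
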