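make_events <- function(scatter, fluorescence, well = "A1") {
  tibble::tibble(well_id = well, event_index = seq_along(scatter),
                 scatter = scatter, fluorescence = fluorescence)
}

test_that("gating below all scatter values is the identity", {
  ev <- make_events(c(100, 200, 300), c(1, 2, 3))
  expect_equal(gate_events(ev, threshold = 50), ev)
})

test_that("gating removes exactly the planted background", {
  set.seed(1)
  bg <- make_events(runif(100, 10, 20), runif(100, 1, 5))
  cells <- make_events(runif(900, 1000, 2000), runif(900, 100, 500))
  ev <- dplyr::bind_rows(cells, bg)
  ev$event_index <- seq_len(nrow(ev))
  gated <- gate_events(ev, threshold = 500)
  expect_equal(nrow(gated), 900)
  expect_true(all(gated$scatter >= 1000))
})

test_that("an empty gate is an error naming the well", {
  ev <- make_events(c(1, 2, 3), c(1, 2, 3), well = "B7")
  expect_error(gate_events(ev, threshold = 10), "B7")
})

test_that("percentile gating trims the per-well lower scatter tail", {
  set.seed(2)
  ev <- dplyr::bind_rows(
    make_events(runif(1000), runif(1000), well = "A1"),
    make_events(runif(1000) + 5, runif(1000), well = "A2")
  )
  gated <- gate_events(ev, percentile = 10)
  counts <- table(gated$well_id)
  expect_true(all(counts >= 890 & counts <= 910))
})

test_that("well means are arithmetic means of gated fluorescence", {
  expect_equal(well_means(make_events(1:3 * 100, c(500, 500, 500)),
                          min_events = 1)$mean_fluorescence, 500)
  expect_equal(well_means(make_events(1:3 * 100, c(100, 200, 300)),
                          min_events = 1)$mean_fluorescence, 200)
})

test_that("a large log-normal well mean matches the closed form", {
  cfg <- sim_config(seed = 4, n_mutants = 1, event_count_per_well = 50000,
                    replicate_log_sd = 0, background_fraction = 0)
  truth <- generate_truth(cfg)[1, ]
  ev <- simulate_events(truth, "uninduced", cfg, seed = 12)
  m <- well_means(ev)$mean_fluorescence
  mu <- truth$uninduced_mean_true
  se <- mu * sqrt((exp(cfg$event_log_sd^2) - 1) / 50000)
  expect_lt(abs(m - mu), 3 * se)
})

test_that("sparse wells are flagged and excluded downstream", {
  ev <- dplyr::bind_rows(
    make_events(rep(1000, 5), rep(100, 5), well = "A1"),
    make_events(rep(1000, 200), rep(100, 200), well = "A2")
  )
  expect_warning(out <- well_means(ev, min_events = 100), "A1")
  expect_false(out$qc_pass[out$well_id == "A1"])
  expect_true(out$qc_pass[out$well_id == "A2"])
})

test_that("strain summaries use n-1 SDs and the exact fold ratio", {
  wells <- tibble::tibble(
    strain_id = "X",
    condition = rep(c("uninduced", "induced"), each = 3),
    replicate = rep(1:3, 2),
    mean_fluorescence = c(2, 4, 6, 20, 20, 20)
  )
  s <- summarize_induction(wells)
  expect_equal(s$mean_uninduced, 4)
  expect_equal(s$sd_uninduced, 2)
  expect_equal(s$sd_induced, 0)
  expect_equal(s$fold_induction, 5)

  wt <- tibble::tibble(
    strain_id = "RbsB",
    condition = rep(c("uninduced", "induced"), each = 3),
    replicate = rep(1:3, 2),
    mean_fluorescence = c(rep(2851, 3), rep(23663, 3))
  )
  s_wt <- summarize_induction(wt)
  expect_equal(s_wt$fold_induction, 23663 / 2851)
  expect_equal(rha(s_wt$fold_induction, 2), 8.30)
})

test_that("summaries reject incomplete or degenerate designs", {
  one_cond <- tibble::tibble(strain_id = "X", condition = "induced",
                             replicate = 1:3,
                             mean_fluorescence = c(1, 2, 3))
  expect_error(summarize_induction(one_cond), "missing a condition")

  zero <- tibble::tibble(
    strain_id = "Z", condition = rep(c("uninduced", "induced"), each = 2),
    replicate = rep(1:2, 2), mean_fluorescence = c(0, 0, 5, 5)
  )
  expect_error(summarize_induction(zero), "undefined")

  single_rep <- tibble::tibble(
    strain_id = "Y", condition = c("uninduced", "induced"),
    replicate = 1, mean_fluorescence = c(1, 2)
  )
  expect_error(summarize_induction(single_rep), "2 replicate")
})

test_that("library thresholds match the direct mean +/- 2 SD formula", {
  base <- tibble::tibble(
    strain_id = paste0("S", 1:5),
    mean_uninduced = 1:5, sd_uninduced = 0,
    mean_induced = 1:5, sd_induced = 0,
    fold_induction = 1, n_replicates = 3L
  )
  thr <- induction_thresholds(base, min_strains = 5)
  expect_equal(thr$mean_uninduced_all, 3)
  expect_equal(thr$sd_uninduced_all, sd(1:5))
  expect_equal(thr$upper_uninduced, 3 + 2 * sd(1:5))
  expect_equal(thr$lower_induced, 3 - 2 * sd(1:5))

  flat <- dplyr::mutate(base, mean_uninduced = 7, mean_induced = 7)
  thr_flat <- induction_thresholds(flat, min_strains = 5)
  expect_equal(thr_flat$upper_uninduced, 7)
  expect_equal(thr_flat$lower_induced, 7)

  expect_error(induction_thresholds(base), "At least 10")
  expect_s3_class(glance(thr), "tbl_df")
})

test_that("threshold recovery on a simulated library", {
  cfg <- sim_config(seed = 19, n_mutants = 232, event_count_per_well = 500)
  sim <- simulate_library(cfg)
  gated <- gate_events(sim$events, percentile = 5)
  wells <- well_means(gated, sim$platemap)
  thr <- induction_thresholds(summarize_induction(wells))
  truth_all <- c(sim$truth$uninduced_mean_true, cfg$baseline_uninduced_mean)
  expected_upper <- mean(truth_all) + 2 * sd(truth_all)
  expect_lt(abs(thr$upper_uninduced / expected_upper - 1), 0.1)
})

test_that("classification follows the ordered threshold rules", {
  wt_like <- tibble::tibble(
    strain_id = paste0("W", 1:25),
    mean_uninduced = 2851, sd_uninduced = 100,
    mean_induced = 23663, sd_induced = 500,
    fold_induction = 23663 / 2851, n_replicates = 3L
  )
  cases <- tibble::tibble(
    strain_id = c("L6", "P262", "N105"),
    mean_uninduced = c(2293, 1906, 8344),
    sd_uninduced = c(107, 418, 171),
    mean_induced = c(1495, 6004, 35539),
    sd_induced = c(34, 1649, 219),
    fold_induction = c(1495 / 2293, 6004 / 1906, 35539 / 8344),
    n_replicates = 3L
  )
  lib <- dplyr::bind_rows(wt_like, cases)
  thr <- induction_thresholds(lib)
  out <- classify_induction(lib, thr)
  got <- setNames(as.character(out$induction_class), out$strain_id)
  expect_equal(got[["L6"]], "non_inducible")
  expect_equal(got[["P262"]], "poorly_inducible")
  expect_equal(got[["N105"]], "semi_constitutive")
  expect_true(all(got[paste0("W", 1:25)] == "wild_type_like"))
  # totality: exactly one label each
  expect_false(any(is.na(out$induction_class)))
})

test_that("classification is invariant under common rescaling", {
  cfg <- sim_config(seed = 23, n_mutants = 40, event_count_per_well = 300)
  sim <- simulate_library(cfg)
  wells <- well_means(gate_events(sim$events), sim$platemap)
  s <- summarize_induction(wells)
  ref <- classify_induction(s, induction_thresholds(s))$induction_class
  for (c_scale in c(0.25, 3, 40)) {
    s2 <- dplyr::mutate(s, dplyr::across(
      c("mean_uninduced", "sd_uninduced", "mean_induced", "sd_induced"),
      ~ .x * c_scale
    ))
    got <- classify_induction(s2, induction_thresholds(s2))$induction_class
    expect_equal(got, ref)
  }
})
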