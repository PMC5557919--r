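test_that("degenerate proportions plant a single class with valid folds", {
  cfg <- sim_config(
    seed = 3, n_mutants = 5,
    class_proportions = c(non_inducible = 1, poorly_inducible = 0,
                          semi_constitutive = 0, wild_type_like = 0)
  )
  truth <- generate_truth(cfg)
  expect_equal(nrow(truth), 5)
  expect_true(all(truth$induction_class_true == "non_inducible"))
  expect_true(all(truth$fold_true <= 1))
  expect_true(all(truth$abundance_multiplier_true > 0))
})

test_that("the same config and seed reproduce the truth table exactly", {
  cfg <- tiny_config(seed = 9)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  expect_identical(simulate_library(cfg), simulate_library(cfg))
})

test_that("planted class counts stay inside the multinomial 99% envelope", {
  cfg <- sim_config(seed = 21, n_mutants = 232)
  truth <- generate_truth(cfg)
  counts <- table(factor(truth$induction_class_true,
                         levels = alascan:::induction_levels()))
  p <- cfg$class_proportions[alascan:::induction_levels()]
  # oracle: marginal binomial tail quantiles at the configured proportions
  lo <- qbinom(0.005, 232, p)
  hi <- qbinom(0.995, 232, p)
  expect_true(all(as.vector(counts) >= lo & as.vector(counts) <= hi))
})

test_that("class frequencies converge to the configured proportions", {
  cfg <- sim_config(seed = 5, n_mutants = 10000)
  truth <- generate_truth(cfg)
  counts <- table(factor(truth$induction_class_true,
                         levels = alascan:::induction_levels()))
  p <- cfg$class_proportions[alascan:::induction_levels()]
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = as.vector(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("wild-type-like planted folds stay within the configured window", {
  cfg <- sim_config(seed = 13, n_mutants = 400)
  truth <- generate_truth(cfg)
  wt_like <- truth[truth$induction_class_true == "wild_type_like", ]
  ratio <- wt_like$fold_true / cfg$wild_type_fold
  expect_true(all(ratio < cfg$wt_fold_window & ratio > 1 / cfg$wt_fold_window))
})

test_that("planted categories obey the categorization rules on true values", {
  cfg <- sim_config(seed = 17, n_mutants = 300)
  truth <- generate_truth(cfg)
  semi_low <- truth$induction_class_true == "semi_constitutive" &
    truth$abundance_multiplier_true < cfg$band$lower
  expect_true(all(truth$category_true[semi_low] == "abundance"))
  impaired <- truth$induction_class_true %in%
    c("non_inducible", "poorly_inducible")
  normal_a <- truth$abundance_multiplier_true >= cfg$band$lower &
    truth$abundance_multiplier_true <= cfg$band$upper
  expect_true(all(truth$category_true[impaired & normal_a] == "signaling"))
})

test_that("event simulation honours background fraction and dispersion", {
  cfg <- tiny_config(seed = 2, background_fraction = 0,
                     event_count_per_well = 500)
  truth <- generate_truth(cfg)[1, ]
  ev <- simulate_events(truth, "uninduced", cfg, seed = 4)
  # no background: every event passes an absolute gate at the floor between
  # the background and cell scatter populations
  expect_equal(nrow(gate_events(ev, threshold = 1e4)), 500)

  cfg0 <- tiny_config(seed = 2, event_log_sd = 1e-12, replicate_log_sd = 0,
                      background_fraction = 0)
  ev0 <- simulate_events(truth, "uninduced", cfg0, seed = 4)
  expect_equal(ev0$fluorescence,
               rep(truth$uninduced_mean_true, nrow(ev0)),
               tolerance = 1e-6)
})

test_that("a fold of one gives equal gated means in both conditions", {
  cfg <- sim_config(seed = 8, n_mutants = 1, event_count_per_well = 20000,
                    replicate_log_sd = 0, background_fraction = 0.05)
  truth <- generate_truth(cfg)[1, ]
  truth$fold_true <- 1
  ev_u <- simulate_events(truth, "uninduced", cfg, seed = 31)
  ev_i <- simulate_events(truth, "induced", cfg, seed = 32)
  m_u <- mean(gate_events(ev_u, threshold = 1e4)$fluorescence)
  m_i <- mean(gate_events(ev_i, threshold = 1e4)$fluorescence)
  # oracle: analytic SE of a log-normal mean ratio,
  # se(ratio) ~ sqrt(2) * sqrt(exp(sd^2) - 1) / sqrt(n)
  n <- 19000
  se_ratio <- sqrt(2 * (exp(cfg$event_log_sd^2) - 1) / n)
  expect_lt(abs(m_i / m_u - 1), 3 * se_ratio)
})

test_that("spectral counts follow the planted abundance and batch factors", {
  cfg <- sim_config(seed = 6, n_mutants = 1,
                    ms_batch_factors = c(b1 = 1, b2 = 2))
  truth <- generate_truth(cfg)[1, ]

  truth0 <- truth
  truth0$abundance_multiplier_true <- 0
  s0 <- simulate_spectral_sample(truth0, cfg, "b1", seed = 1)
  expect_equal(s0$target_count, 0)

  expect_identical(simulate_spectral_sample(truth, cfg, "b1", seed = 7),
                   simulate_spectral_sample(truth, cfg, "b1", seed = 7))
  expect_error(simulate_spectral_sample(truth, cfg, "b9"), "b9")

  set.seed(99)
  reps <- function(batch) {
    mean(purrr::map_dbl(1:30,
                        ~ simulate_spectral_sample(truth, cfg, batch)$target_count))
  }
  m1 <- reps("b1"); m2 <- reps("b2")
  mu <- truth$abundance_multiplier_true * cfg$wt_target_rate * cfg$ms_depth_mean
  # oracle: Poisson mean ratio, se ~ sqrt(1/n1/mu1 + 1/n2/mu2) on the log scale
  se_log <- sqrt(1 / (30 * mu) + 1 / (30 * 2 * mu))
  expect_lt(abs(log(m2 / m1) - log(2)), 4 * se_log)
})

test_that("total spectra never undercount the component proteins", {
  cfg <- tiny_config(seed = 15)
  sim <- simulate_library(cfg)
  expect_true(all(sim$spectral$target_count + sim$spectral$standard_count <=
                    sim$spectral$total_spectra))
  # wild-type anchor present once per batch
  anchors <- sim$spectral[sim$spectral$strain_id == "RbsB", ]
  expect_setequal(anchors$batch, names(cfg$ms_batch_factors))
  expect_equal(nrow(anchors), length(cfg$ms_batch_factors))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_mutants = 5), "seed")
  expect_error(
    sim_config(seed = 1, class_proportions = c(non_inducible = 0.5,
                                               poorly_inducible = 0.2,
                                               semi_constitutive = 0.2,
                                               wild_type_like = 0.2)),
    "sum to 1"
  )
  expect_error(sim_config(seed = 1, replicates = 1), "replicates")
  expect_error(sim_config(seed = 1, background_fraction = 1), "background")
})
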