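test_that("a single free rate is recovered from noise-free data", {
  true_k <- 0.5
  m <- chain_model(k_up = 2, k_out = true_k)
  prot <- labeling_protocol("bicarbonate", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0,
                             n_replicates = 3, seed = 1)
  fit <- fit_pool_model(tc, chain_model(k_up = 2, k_out = 1), "S->T",
                        n_starts = 4, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$rates[["S->T"]] - true_k) / true_k, 1e-4)
})

test_that("an absent pathway is estimated at the zero bound", {
  m <- pla_pool_model(k_pl_tag = 0, k_pl_loss = 0.2, tag_onset_lag = 0)
  prot <- labeling_protocol("palmitic_acid", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0,
                             n_replicates = 3, seed = 2)
  fit <- fit_pool_model(tc, pla_pool_model(tag_onset_lag = 0),
                        c("polar_lipid->TAG", "polar_lipid->loss"),
                        n_starts = 4, seed = 2)
  expect_lt(fit$rates[["polar_lipid->TAG"]], 1e-5)
})

test_that("refitting from the solution returns the solution", {
  m <- chain_model(k_up = 2, k_out = 0.5)
  prot <- labeling_protocol("bicarbonate", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0.1,
                             n_replicates = 3, seed = 3)
  fit <- fit_pool_model(tc, m, "S->T", n_starts = 4, seed = 3)
  refit <- fit_pool_model(tc, m, "S->T", init = fit$rates, n_starts = 1,
                          seed = 3)
  expect_lte(refit$rss, fit$rss + 1e-8)
  expect_equal(refit$rates, fit$rates, tolerance = 1e-5)
})

test_that("fitted transfer fractions follow the linear system", {
  # single outgoing edge: everything eventually reaches the sink
  one <- pla_pool_model(k_pl_tag = 0.4, k_pl_loss = 0)
  expect_equal(fitted_transfer_fraction(one, "polar_lipid", "TAG",
                                        horizon = 200), 1, tolerance = 1e-6)
  # two equal competing edges split the label evenly
  two <- pla_pool_model(k_pl_tag = 0.4, k_pl_loss = 0.4)
  expect_equal(fitted_transfer_fraction(two, "polar_lipid", "TAG",
                                        horizon = 200), 0.5,
               tolerance = 1e-6)
  expect_error(fitted_transfer_fraction(two, "polar_lipid", "nope"),
               class = "tagflux_input_error")
})

test_that("fitted fractions agree with the arithmetic estimator when clean", {
  m <- pla_pool_model(k_pl_tag = 0.3, k_pl_loss = 0.1, tag_onset_lag = 0)
  prot <- labeling_protocol("palmitic_acid", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0,
                             n_replicates = 3, seed = 4)
  fit <- fit_pool_model(tc, pla_pool_model(tag_onset_lag = 0),
                        c("polar_lipid->TAG", "polar_lipid->loss"),
                        n_starts = 4, seed = 4)
  arith <- attr(pl_transfer_fractions(tc), "cumulative")
  fitted <- fitted_transfer_fraction(fit, "polar_lipid", "TAG", horizon = 7)
  expect_lt(abs(fitted - arith), 0.02)
})

test_that("rate recovery under replicate noise stays within 15% (median)", {
  true_rates <- c(`polar_lipid->TAG` = 0.385, `polar_lipid->loss` = 0.08)
  errs <- sapply(1:20, function(s) {
    ds <- generate_paperlike_dataset(seed = s)
    fit <- fit_pool_model(ds$pre_n_pla_chase, pla_pool_model(),
                          c("polar_lipid->TAG", "polar_lipid->loss"),
                          n_starts = 4, seed = s)
    abs(fit$rates - true_rates) / true_rates
  })
  expect_lte(median(errs["polar_lipid->TAG", ]), 0.15)
})

test_that("bootstrap intervals contain the point estimates", {
  m <- chain_model(k_up = 2, k_out = 0.5)
  prot <- labeling_protocol("bicarbonate", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0.1,
                             n_replicates = 3, seed = 5)
  fit <- fit_pool_model(tc, m, "S->T", n_starts = 2, seed = 5, nboot = 20)
  expect_false(is.null(fit$intervals))
  expect_true(all(fit$intervals$lower <= fit$intervals$estimate))
  expect_true(all(fit$intervals$upper >= fit$intervals$estimate))
})

test_that("underdetermined fits are rejected or flagged, not silent", {
  m <- chain_model()
  prot <- labeling_protocol("bicarbonate", 0, 1, 2)
  tc <- simulate_pulse_chase(m, prot, grid = 1, noise_cv = 0,
                             n_replicates = 1, seed = 1, pools = "T")
  expect_error(fit_pool_model(tc, m, c("ext->S", "S->T"), pools = "T",
                              protocol = prot),
               class = "tagflux_input_error")
  tc2 <- simulate_pulse_chase(m, prot, grid = c(1, 2), noise_cv = 0,
                              n_replicates = 1, seed = 1, pools = "T")
  expect_warning(fit_pool_model(tc2, m, c("ext->S", "S->T"), pools = "T",
                                protocol = prot, n_starts = 2),
                 "unidentifiable")
})
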