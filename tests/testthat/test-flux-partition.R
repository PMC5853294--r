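test_that("pooled source series takes clamped first differences", {
  tc <- make_tc(list(starch = c(300, 120), soluble = c(0, 0),
                     TAG = c(20, 200)), days = c(0, 8))
  ts <- pooled_source_series(tc, c("starch", "soluble"), "TAG")
  expect_equal(ts$source_decrease, 180)
  expect_equal(ts$sink_increase, 180)

  flat <- make_tc(list(starch = c(50, 50, 50), TAG = c(5, 5, 5)), days = 0:2)
  ts2 <- pooled_source_series(flat, "starch", "TAG")
  expect_equal(ts2$source_decrease, c(0, 0))
  expect_equal(ts2$sink_increase, c(0, 0))

  # clamping never increases a transfer estimate
  noisy <- make_tc(list(starch = c(100, 110, 60), TAG = c(10, 5, 30)),
                   days = 0:2)
  ts3 <- pooled_source_series(noisy, "starch", "TAG")
  un <- attr(ts3, "unclamped")
  expect_true(all(ts3$source_decrease <= pmax(un$source_decrease, 0) + 1e-12))
  expect_equal(ts3$source_decrease, pmax(0, un$source_decrease))
  expect_equal(ts3$sink_increase, pmax(0, un$sink_increase))
})

test_that("conversion efficiency reproduces the published chase ratios", {
  expect_equal(conversion_efficiency(transfer_series(300, 180)), 0.60)
  expect_equal(conversion_efficiency(transfer_series(12, 9)), 0.75)
  expect_equal(conversion_efficiency(transfer_series(c(5, 5), c(0, 0))), 0)
  expect_error(conversion_efficiency(transfer_series(0, 0)),
               class = "tagflux_undefined_error")
  expect_warning(conversion_efficiency(transfer_series(10, 15)),
                 "exceeds 1")
})

test_that("a closed simulated chase has efficiency 1", {
  m <- chain_model(k_up = 3, k_out = 0.4)
  prot <- labeling_protocol("bicarbonate", 0, 1, 9)
  tc <- simulate_pulse_chase(m, prot, grid = 1:9, noise_cv = 0,
                             n_replicates = 1, seed = 1)
  eff <- conversion_efficiency(pooled_source_series(tc, "S", "T"))
  expect_equal(eff, 1, tolerance = 1e-6)
  # with noise_cv = 0, clamping is a no-op
  ts <- pooled_source_series(tc, "S", "T")
  un <- attr(ts, "unclamped")
  expect_equal(ts$source_decrease, un$source_decrease)
  expect_equal(ts$sink_increase, un$sink_increase)
})

test_that("daily starch-to-TAG contributions sum pulse-chase appearances", {
  flat <- lapply(1:8, function(p) {
    make_tc(list(TAG = rep(7, 9 - p), starch = rep(100, 9 - p)),
            days = p:8, label_end = p,
            experiment = sprintf("pulse%d", p))
  })
  expect_equal(unname(starch_to_tag_daily(flat)), rep(0, 8))

  # two toy pulses with known appearances
  p1 <- make_tc(list(TAG = c(0, 10, 25, 25)), days = 1:4, label_end = 1)
  p2 <- make_tc(list(TAG = c(5, 5, 12)), days = 2:4, label_end = 2)
  out <- starch_to_tag_daily(list(p1, p2), days = 1:4)
  expect_equal(unname(out), c(0, 10, 15, 7))
})

test_that("daily starch-to-TAG recovery matches the simulator", {
  # starch -> TAG only, known rate; estimates track the noise-free truth
  m <- bicarbonate_pool_model(k_sol_pl = 0, k_sol_tag = 0)
  mk <- function(noise, seed) lapply(1:8, function(p) {
    simulate_pulse_chase(m, labeling_protocol("bicarbonate", p - 1, p, 8),
                         grid = p:8, noise_cv = noise, n_replicates = 3,
                         seed = seed + p,
                         experiment = sprintf("pulse%d", p))
  })
  truth <- starch_to_tag_daily(mk(0, 0))
  cv <- 0.05
  est <- starch_to_tag_daily(mk(cv, 100))
  # each day's estimate sums <= 8 clamped differences of 3-replicate means
  tol <- 3 * cv * max(truth) * sqrt(2 / 3) * sqrt(8)
  expect_true(all(abs(est - truth) <= tol))
})

test_that("direct de novo and PL synthesis read the label-end samples", {
  pulses <- lapply(1:8, function(p) {
    make_tc(list(TAG = seq(p, 10, length.out = 9 - p),
                 polar_lipid = rep(2 * p, 9 - p)),
            days = p:8, label_end = p, experiment = sprintf("pulse%d", p))
  })
  expect_equal(unname(de_novo_direct_daily(pulses)), as.numeric(1:8))
  expect_equal(unname(pl_daily_synthesis(pulses)), as.numeric(2 * (1:8)))
  expect_error(de_novo_direct_daily(pulses[1:3]),
               class = "tagflux_input_error")
  # zero TAG label at all label ends -> all-zero series
  zero <- lapply(1:8, function(p) {
    make_tc(list(TAG = c(0, rep(3, 8 - p))), days = p:8, label_end = p)
  })
  expect_equal(unname(de_novo_direct_daily(zero)), rep(0, 8))
})

test_that("PL transfer fractions follow the chase arithmetic", {
  tc <- make_tc(list(polar_lipid = c(100, 60, 30, 30),
                     TAG = c(0, 40, 70, 70)),
                days = 1:4, label_end = 1)
  fr <- pl_transfer_fractions(tc)
  expect_equal(fr$fraction, c(0.40, 0.30, 0))
  expect_equal(attr(fr, "cumulative"), 0.70)

  flat <- make_tc(list(polar_lipid = c(50, 50), TAG = c(5, 5)),
                  days = 1:2, label_end = 1)
  expect_equal(pl_transfer_fractions(flat)$fraction, 0)

  none <- make_tc(list(polar_lipid = c(0, 0), TAG = c(0, 1)),
                  days = 1:2, label_end = 1)
  expect_error(pl_transfer_fractions(none), class = "tagflux_undefined_error")

  # cumulative fraction is capped at 1
  hot <- make_tc(list(polar_lipid = c(10, 1, 1), TAG = c(0, 8, 16)),
                 days = 1:3, label_end = 1)
  fr2 <- pl_transfer_fractions(hot)
  expect_lte(attr(fr2, "cumulative"), 1)
  expect_equal(sum(fr2$fraction), 1)
})

test_that("simulated PL chases match the analytic transfer fraction", {
  # single PL -> TAG edge, no gate: cumulative fraction is 1 - exp(-k T)
  k <- 0.3
  m <- pla_pool_model(k_pl_tag = k, k_pl_loss = 0, tag_onset_lag = 0)
  prot <- labeling_protocol("palmitic_acid", 0, 1, 8)
  tc <- simulate_pulse_chase(m, prot, grid = 1:8, noise_cv = 0,
                             n_replicates = 1, seed = 1)
  fr <- pl_transfer_fractions(tc)
  expect_lt(abs(attr(fr, "cumulative") - (1 - exp(-k * 7))), 0.05)
})

test_that("the via-PL pathway is the stated convolution", {
  expect_equal(unname(de_novo_via_pl_daily(rep(10, 8), rep(0, 7))), rep(0, 8))
  out <- de_novo_via_pl_daily(c(100, rep(0, 7)), c(0.4, 0.3))
  expect_equal(unname(out), c(0, 40, 30, 0, 0, 0, 0, 0))
  # overlapping synthesis days accumulate
  out2 <- de_novo_via_pl_daily(c(100, 50, rep(0, 6)), c(0.4, 0.3))
  expect_equal(unname(out2), c(0, 40, 50, 15, 0, 0, 0, 0))
  expect_error(de_novo_via_pl_daily(1:3, c(0.4), days = 1:8),
               class = "tagflux_input_error")
  expect_error(de_novo_via_pl_daily(rep(1, 8), c(0.4, 0.8)),
               class = "tagflux_input_error")
})

test_that("partition rows close exactly and validate inputs", {
  ref <- read_reference_table()
  p <- assemble_partition(ref$from_starch, ref$de_novo_direct,
                          ref$de_novo_via_pl, ref$total_measured)
  expect_equal(p$total_calculated[p$day == 2], 61.2)
  expect_equal(p$total_calculated[p$day == 5], 51.3)
  expect_equal(p$total_calculated, with(ref, from_starch + de_novo_direct +
                                          de_novo_via_pl))
  z <- assemble_partition(rep(0, 8), rep(0, 8), rep(0, 8), rep(0, 8))
  expect_true(all(as.matrix(as.data.frame(z)[, -1]) == 0))
  expect_error(assemble_partition(c(-1, rep(0, 7)), rep(0, 8), rep(0, 8),
                                  rep(0, 8)),
               class = "tagflux_input_error")
  set.seed(3)
  for (i in 1:10) {
    a <- runif(8, 0, 50); b <- runif(8, 0, 50); c <- runif(8, 0, 50)
    pp <- assemble_partition(a, b, c, a + b + c)
    expect_identical(pp$total_calculated, a + b + c)  # exact, full precision
  }
})

test_that("pathway fractions summarize the calculated totals", {
  ref <- read_reference_table()
  p <- assemble_partition(ref$from_starch, ref$de_novo_direct,
                          ref$de_novo_via_pl, ref$total_measured)
  fr <- pathway_fractions(p)
  expect_equal(sum(fr), 1)
  expect_lt(abs(fr[["from_starch"]] - 2 / 3), 0.02)  # "about two-thirds"
  one <- assemble_partition(rep(1, 8), rep(0, 8), rep(0, 8), rep(1, 8))
  expect_equal(unname(pathway_fractions(one)), c(1, 0, 0))
  eq <- assemble_partition(rep(2, 8), rep(2, 8), rep(2, 8), rep(6, 8))
  expect_equal(unname(pathway_fractions(eq)), rep(1 / 3, 3))
})

test_that("the pre-formed PL bound scales and flags consistency", {
  ds <- generate_paperlike_dataset(seed = 2)
  est <- preformed_pl_estimate(ds$pre_n_pla_chase)
  # published assumptions give a bound well under 5 nmol C per 1e6 cells
  expect_lt(est$estimate_nmol_c, 5)
  expect_gt(est$conversion_fraction, 0.5)
  # homogeneous-labeling extrapolation exceeds the PL-decrease cap
  expect_gt(est$homogeneous_estimate_nmol_c, 55)
  expect_false(est$consistent)

  flat <- make_tc(list(polar_lipid = c(12, 10), TAG = c(3, 3)),
                  days = 0:1, tracer = "palmitic_acid", label_end = 0)
  est0 <- preformed_pl_estimate(flat)
  expect_equal(est0$estimate_nmol_c, 0)
  expect_error(preformed_pl_estimate(flat, added_pla_conc = 0),
               class = "tagflux_config_error")
  expect_error(preformed_pl_estimate(flat, internal_pla_conc = NA),
               class = "tagflux_config_error")
})

test_that("relative de novo synthesis compares conditions per lipid class", {
  ctl <- make_tc(list(TAG = c(10, 10), DGDG = c(8, 8), FA = c(20, 20)),
                 days = c(3, 4))
  dep <- make_tc(list(TAG = c(10, 10), DGDG = c(2, 2), FA = c(1, 1)),
                 days = c(3, 4))
  out <- relative_de_novo(ctl, dep, c("TAG", "DGDG", "FA"))
  expect_equal(out$ratio, c(1, 0.25, 0.05))
  expect_equal(out$suppression, c(0, 0.75, 0.95))
  empty <- relative_de_novo(ctl, dep, character(0))
  expect_identical(nrow(empty), 0L)
})
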