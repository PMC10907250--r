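test_that("no drift and no pulses give constant truth and flat ancestry", {
  cfg <- sim_config(n_loci = 200, N_focal = Inf, N_source = Inf,
                    pulse_gens = integer(0), start_gen = 50,
                    sample_gens = c(40, 20, 0))
  sim <- simulate_panel(cfg, seed = 1)
  expect_equal(sim$true_freq[, 1], sim$true_freq[, 2])
  expect_equal(sim$true_freq[, 1], sim$true_freq[, 3])
  expect_equal(unname(sim$trajectory$alpha[, 1]), rep(1, 3))
  expect_equal(sim$truth$total, matrix(0, 2, 2))
})

test_that("a single pulse mixes frequencies and ancestry exactly", {
  cfg <- sim_config(n_loci = 300, N_focal = Inf, N_source = Inf,
                    pulse_gens = 25, pulse_m = 0.5, start_gen = 50,
                    sample_gens = c(40, 0))
  sim <- simulate_panel(cfg, seed = 2)
  # focal was a copy of source 1; after m = 0.5 pulse from source 2 the true
  # frequency is the midpoint and ancestry is (0.5, 0.5)
  p0 <- sim$true_freq[, 1]
  expect_equal(unname(sim$trajectory$alpha[2, ]), c(0.5, 0.5))
  # without drift, all realized change is admixture: truth A = 1 exactly
  # and the recovered source-2 frequency 2*p1 - p0 lies in [0, 1]
  expect_equal(sim$truth$A[1], 1)
  f2 <- 2 * sim$true_freq[, 2] - p0
  expect_true(all(f2 >= 0 & f2 <= 1))
  expect_equal(max(abs(sim$truth$D_true)), 0)
})

test_that("neutral drift matches Wright-Fisher moments", {
  set.seed(33)
  cfg <- sim_config(n_loci = 20000, N_focal = 1000, pulse_gens = integer(0),
                    start_gen = 1, sample_gens = c(1, 0), proxy_gen = 1)
  sim <- simulate_panel(cfg)
  dp <- sim$true_freq[, 2] - sim$true_freq[, 1]
  p <- sim$true_freq[, 1]
  # E[dp] = 0 and Var[dp] = p(1-p)/2N within 3 SE over loci
  expect_lt(abs(mean(dp)), 3 * sd(dp) / sqrt(length(dp)))
  vtheory <- mean(p * (1 - p)) / 2000
  se_v <- sd(dp^2) / sqrt(length(dp))
  expect_lt(abs(mean(dp^2) - vtheory), 3 * se_v)
})

test_that("truth decomposition conserves the realized total variance", {
  sim <- simulate_panel(sim_config(n_loci = 1000, N_focal = 500,
                                   N_source = 500, start_gen = 100,
                                   pulse_gens = c(70, 30),
                                   sample_gens = c(80, 60, 40, 20, 0),
                                   source_drift = TRUE),
                        seed = 4)
  tr <- sim$truth
  recon <- tr$A_true + tr$D_true + tr$cross + t(tr$cross)
  expect_lt(max(abs(recon - tr$total)), 1e-12)
  # ancestry rows sum to 1 exactly
  expect_lt(max(abs(rowSums(sim$trajectory$alpha) - 1)), 1e-12)
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_loci = 500, N_focal = 800, start_gen = 60,
                    pulse_gens = 30, sample_gens = c(40, 20, 0))
  s1 <- simulate_panel(cfg, seed = 11)
  s2 <- simulate_panel(cfg, seed = 11)
  expect_identical(s1$panel$freq, s2$panel$freq)
  expect_identical(s1$sources$freq, s2$sources$freq)
  s3 <- simulate_panel(cfg, seed = 12)
  expect_false(identical(s1$panel$freq, s3$panel$freq))
})

test_that("zero-strength selection overlays reduce to neutrality", {
  cfg <- sim_config(n_loci = 5000, N_focal = 1000, pulse_gens = integer(0),
                    start_gen = 30, sample_gens = c(30, 20, 10, 0))
  neutral <- simulate_panel(cfg, seed = 21)
  null_sel <- simulate_selection(cfg, selection_overlay("directional", s = 0,
                                                        n_selected = 100),
                                 seed = 22)
  dn <- neutral$true_freq[, 4] - neutral$true_freq[, 1]
  ds <- null_sel$true_freq[, 4] - null_sel$true_freq[, 1]
  # same drift-change distribution: compare mean and variance within 4 SE
  expect_lt(abs(mean(dn) - mean(ds)),
            4 * sqrt(var(dn) / 5000 + var(ds) / 5000))
  expect_lt(abs(var(dn) / var(ds) - 1), 0.15)
  # zero selected loci falls back to neutral with a warning
  expect_warning(simulate_selection(cfg, selection_overlay("gss",
                                                           n_selected = 0),
                                    seed = 23),
                 "zero selected")
})

test_that("sustained directional selection builds positive covariance", {
  set.seed(43)
  cfg <- sim_config(n_loci = 4000, N_focal = Inf, pulse_gens = integer(0),
                    start_gen = 40, sample_gens = c(40, 30, 20, 10, 0),
                    overlay = selection_overlay("directional", s = 0.05,
                                                n_selected = 100,
                                                linkage_tightness = 0.8))
  sim <- simulate_panel(cfg, seed = 31)
  d <- sim$true_freq[, -1] - sim$true_freq[, -5]
  M <- crossprod(d) / nrow(d)
  off <- sum(M) - sum(diag(M))
  expect_gt(off, 0)
})

test_that("background-selection overlay yields sustained downward change", {
  cfg <- sim_config(n_loci = 2000, N_focal = Inf, pulse_gens = integer(0),
                    start_gen = 40, sample_gens = c(40, 30, 20, 10, 0),
                    overlay = selection_overlay("bgs", n_selected = 100,
                                                linkage_tightness = 0.8))
  sim <- simulate_panel(cfg, seed = 51)
  expect_true(all(sim$true_freq >= 0 & sim$true_freq <= 1))
  d <- sim$true_freq[, -1] - sim$true_freq[, -5]
  M <- crossprod(d) / nrow(d)
  expect_gt(sum(M) - sum(diag(M)), 0)   # compounding linked change
})

test_that("interval_sweep reports the covariance/variance trade-off", {
  cfg <- sim_config(n_loci = 1000, N_focal = Inf, pulse_gens = integer(0),
                    start_gen = 41, sample_gens = c(40, 0),
                    overlay = selection_overlay("directional", s = 0.05,
                                                n_selected = 50,
                                                linkage_tightness = 0.8))
  sw <- interval_sweep(cfg, sampling_intervals = c(5, 10, 20), span = 40,
                       n_reps = 2, seed = 41)
  expect_setequal(unique(sw$interval), c(5, 10, 20))
  # with pure deterministic selection, covariance shifts into variance as
  # the sampling interval grows
  agg <- aggregate(cbind(sum_cov, sum_var) ~ interval, sw, mean)
  expect_true(all(diff(agg$sum_cov) < 0))
  # neutral overlay -> sums near zero
  cfg0 <- sim_config(n_loci = 1000, N_focal = Inf, pulse_gens = integer(0),
                     start_gen = 41, sample_gens = c(40, 0))
  sw0 <- interval_sweep(cfg0, sampling_intervals = c(5, 10), span = 40,
                        n_reps = 1, seed = 42)
  expect_lt(max(abs(sw0$sum_cov)), 1e-12)
})
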