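test_that("raw covariance matrix matches the naive double-loop oracle", {
  set.seed(11)
  d <- matrix(rnorm(200 * 3, sd = 0.01), 200, 3)
  pan <- panel_from_deltas(d)
  expect_lt(max(abs(raw_cov_matrix(pan) - naive_moment_matrix(d))), 1e-12)
  expect_lt(max(abs(raw_cov_matrix(pan, centered = TRUE) -
                    naive_moment_matrix(d, centered = TRUE))), 1e-12)
})

test_that("degenerate delta structures give the expected raw matrices", {
  pan <- panel_from_deltas(matrix(0, 50, 3))
  expect_equal(raw_cov_matrix(pan), matrix(0, 3, 3), ignore_attr = TRUE)
  # perfectly correlated intervals
  d1 <- rnorm(100, sd = 0.01)
  R <- raw_cov_matrix(panel_from_deltas(cbind(d1, d1)))
  expect_equal(R[1, 1], R[1, 2])
  expect_equal(R[1, 1], R[2, 2])
})

test_that("sampling-bias matrix follows the plug-in noise arithmetic", {
  # single SNP, p = 0.5 at 3 time points, n = 11
  pan <- freq_panel("s1", "1", 1, rbind(c(0.5, 0.5, 0.5)),
                    rbind(c(11, 11, 11)))
  Ss <- sampling_bias_matrix(pan)
  expect_equal(diag(Ss), rep(0.25 / 10 + 0.25 / 10, 2), ignore_attr = TRUE)
  expect_equal(Ss[1, 2], -0.25 / 10)
  # structure: zero beyond the first off-diagonal
  pan5 <- sampled_panel(100, 5, n = 20)
  Ss4 <- sampling_bias_matrix(pan5)
  expect_equal(Ss4[1, 3], 0); expect_equal(Ss4[1, 4], 0)
  expect_equal(Ss4[2, 4], 0)
  expect_true(all(diag(Ss4) > 0))
  expect_true(all(Ss4[cbind(1:3, 2:4)] < 0))
  # n -> infinity limit
  pan_inf <- freq_panel("s1", "1", 1, rbind(c(0.5, 0.4, 0.3)),
                        rbind(c(1e9, 1e9, 1e9)))
  expect_lt(max(abs(sampling_bias_matrix(pan_inf))), 1e-8)
})

test_that("resampling noise is removed by Ss (Monte-Carlo)", {
  set.seed(21)
  pan <- sampled_panel(20000, 3, n = 30, window_size = 20000)
  cs <- corrected_cov_matrix(pan)
  d <- pan$freq[, -1] - pan$freq[, -3]
  se <- sqrt(diag(crossprod(d^2)) / nrow(d)) / sqrt(nrow(d)) # SE of moments
  expect_true(all(abs(cs$C) <= 3 * max(se, 1e-5) + 3e-5))
  # raw first off-diagonal is negative, matching Ss's shared-sample term
  expect_lt(cs$R[1, 2], 0)
})

test_that("admixture-predicted changes match the triple-loop oracle", {
  set.seed(31)
  L <- 40; R <- 3; K <- 4
  alpha <- matrix(runif((K + 1) * R), K + 1, R)
  alpha <- alpha / rowSums(alpha)
  traj <- ancestry_traj(alpha)
  src <- source_panel(paste0("s", 1:L), matrix(runif(L * R), L, R),
                      matrix(50, L, R))
  dA <- admixture_predicted_changes(traj, src)
  oracle <- matrix(0, L, K)
  for (l in seq_len(L)) for (i in seq_len(K)) for (r in seq_len(R))
    oracle[l, i] <- oracle[l, i] + traj$delta_alpha[i, r] * src$freq[l, r]
  expect_lt(max(abs(dA - oracle)), 1e-12)
  # matrix equals oracle covariance of predicted-change columns
  A <- admixture_cov_matrix(traj, src)
  expect_lt(max(abs(A - naive_moment_matrix(oracle))), 1e-12)
})

test_that("admixture change and covariance behave for simple pulses", {
  # zero ancestry change -> all-zero matrices
  traj0 <- ancestry_traj(matrix(c(0.6, 0.4), 4, 2, byrow = TRUE))
  src <- source_panel(paste0("s", 1:20), matrix(runif(40), 20, 2),
                      matrix(30, 20, 2))
  expect_equal(admixture_predicted_changes(traj0, src),
               matrix(0, 20, 3), ignore_attr = TRUE)
  # two-source pulse: delta_alpha = (+m, -m) with f = (1, 0) gives m... via
  # flipped roles: pulse from source 2 of size m with f2 = 1, f1 = 0
  m <- 0.25
  traj <- traj_from_pulses(m)
  src10 <- source_panel(paste0("s", 1:5), cbind(rep(0, 5), rep(1, 5)),
                        matrix(1e9, 5, 2))
  expect_equal(admixture_predicted_changes(traj, src10)[, 1], rep(m, 5))
  # single pulse in interval 1 only -> A nonzero only at (1,1)
  traj2 <- traj_from_pulses(c(0.3, 0))
  srcr <- source_panel(paste0("s", 1:50), matrix(runif(100), 50, 2),
                       matrix(1e9, 50, 2))
  A <- admixture_cov_matrix(traj2, srcr)
  expect_gt(A[1, 1], 0)
  expect_equal(A[2, 2], 0); expect_equal(A[1, 2], 0)
  # two same-direction pulses -> positive off-diagonal
  A2 <- admixture_cov_matrix(traj_from_pulses(c(0.2, 0.2)), srcr)
  expect_gt(A2[1, 2], 0)
})

test_that("proxy sampling bias SA has the right limits and signs", {
  set.seed(41)
  L <- 500
  src <- source_panel(paste0("s", 1:L), matrix(runif(2 * L, 0.2, 0.8), L, 2),
                      matrix(30, L, 2))
  # opposite-direction ancestry changes from one source -> SA[1,2] < 0
  alpha <- rbind(c(0.5, 0.5), c(0.3, 0.7), c(0.5, 0.5))
  traj <- ancestry_traj(alpha)
  SA <- admixture_sampling_bias(traj, src)
  expect_lt(SA[1, 2], 0)
  expect_gt(SA[1, 1], 0)
  # n -> infinity limit
  src_inf <- source_panel(src$snp_id, src$freq, matrix(1e9, L, 2))
  expect_lt(max(abs(admixture_sampling_bias(traj, src_inf))), 1e-8)
})

test_that("drift-admixture interaction D has the documented structure", {
  # no admixture anywhere -> D = 0
  traj0 <- ancestry_traj(matrix(c(0.7, 0.3), 4, 2, byrow = TRUE))
  expect_equal(drift_admixture_interaction(traj0, rep(0.01, 3)),
               matrix(0, 3, 3))
  # zero drift variance -> D = 0
  traj <- traj_from_pulses(c(0.1, 0.2, 0.1))
  expect_equal(drift_admixture_interaction(traj, rep(0, 3)),
               matrix(0, 3, 3))
  # closed form from the standing-drift recursion (m = 0.1, 0.2, 0.1):
  # W1 = 0, U1 = V1, eff1 = V1; U2 = V2 - m2^2 W2, eff2 = U2 - m2(1-m2)W2
  V <- c(0.01, 0.02, 0.005)
  D <- drift_admixture_interaction(traj, V)
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D[1, 2], -0.2 * V[1])
  expect_equal(D[1, 3], -0.1 * (1 - 0.2) * V[1])
  eff2 <- (V[2] - 0.2^2 * V[1]) - 0.2 * 0.8 * V[1]
  expect_equal(D[2, 3], -0.1 * eff2)
  expect_equal(D, t(D))
  # two gaining sources in one interval violate the model assumption
  alpha_bad <- rbind(c(1, 0, 0), c(0.6, 0.2, 0.2))
  traj_bad <- ancestry_traj(alpha_bad)
  expect_error(drift_admixture_interaction(traj_bad, 0.01),
               "single parental")
})

test_that("corrected matrix reduces to R - Ss when no ancestry changes", {
  set.seed(51)
  pan <- sampled_panel(500, 4, n = 25, window_size = 250)
  src <- source_panel(pan$snp_id, matrix(runif(1000), 500, 2),
                      matrix(30, 500, 2))
  traj0 <- ancestry_traj(matrix(c(0.6, 0.4), 4, 2, byrow = TRUE))
  cs <- corrected_cov_matrix(pan, traj0, src)
  expect_equal(cs$C, cs$R - cs$Ss)
  expect_equal(cs$A_adm, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(cs$D, matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("all matrices are invariant to reference-allele flips", {
  set.seed(61)
  pan <- sampled_panel(400, 4, n = 30, window_size = 100)
  src <- source_panel(pan$snp_id, matrix(runif(800, 0.1, 0.9), 400, 2),
                      matrix(30, 400, 2))
  traj <- traj_from_pulses(c(0.1, 0, 0.2))
  cs <- corrected_cov_matrix(pan, traj, src)
  fl <- flip_polarity(pan, src, sample.int(400, 150))
  cs_f <- corrected_cov_matrix(fl$panel, traj, fl$sources)
  for (nm in c("R", "Ss", "A_adm", "SA", "D", "C"))
    expect_lt(max(abs(cs[[nm]] - cs_f[[nm]])), 1e-12)
})

test_that("window aggregation equals the direct all-SNP computation", {
  set.seed(71)
  pan <- sampled_panel(600, 3, n = 30)
  pan_w <- assign_windows(pan, 100)
  pan_1 <- assign_windows(pan, 600)
  cs_w <- corrected_cov_matrix(pan_w)
  cs_1 <- corrected_cov_matrix(pan_1)
  expect_lt(max(abs(cs_w$R - cs_1$R)), 1e-14)
  expect_lt(max(abs(cs_w$Ss - cs_1$Ss)), 1e-14)
  # and the weighted mean of per-window matrices is that same aggregate
  Rw <- Reduce(`+`, lapply(cs_w$per_window, function(w) w$R * w$m))
  expect_lt(max(abs(Rw / sum(cs_w$weights) - cs_1$R)), 1e-14)
})

test_that("symmetry and composition identities hold", {
  set.seed(81)
  pan <- sampled_panel(300, 4, n = 30, window_size = 150)
  src <- source_panel(pan$snp_id, matrix(runif(600, 0.2, 0.8), 300, 2),
                      matrix(40, 300, 2))
  traj <- traj_from_pulses(c(0.15, 0.1, 0))
  cs <- corrected_cov_matrix(pan, traj, src)
  for (nm in c("R", "Ss", "A_adm", "SA", "D", "C"))
    expect_equal(cs[[nm]], t(cs[[nm]]))
  expect_equal(cs$C, (cs$R - cs$Ss) - (cs$A_adm - cs$SA) - cs$D)
  cs_add <- corrected_cov_matrix(pan, traj, src, sa_sign = "add")
  expect_equal(cs_add$C + cs_add$D + cs_add$A_adm + cs_add$SA,
               cs_add$R - cs_add$Ss)
})
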