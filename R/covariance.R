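# Temporal covariance machinery.
#
# All across-SNP (co)moments default to the uncentered mean of products of
# per-interval allele-frequency changes.  E[dp] = 0 under drift, and the
# uncentered moment is exactly invariant to flipping the reference allele at
# any subset of SNPs (dp -> -dp SNP-wise), an invariant every downstream
# statistic inherits.  `centered = TRUE` subtracts the per-window,
# per-interval across-SNP mean change (absorbing systematic artifacts such as
# reference bias) at the cost of exact polarity invariance.
#
# Denominator is the SNP count (not count - 1) so that the SNP-count-weighted
# mean of per-window matrices is algebraically identical to the pooled
# all-SNP computation.

# Mean of products of columns of d across rows, honouring NA masks.
# Returns K x K moment matrix M and per-entry contributing-SNP counts.
masked_cross_moment <- function(d, centered = FALSE) {
  obs <- !is.na(d)
  counts <- crossprod(obs)
  if (centered) {
    mu <- colSums(d, na.rm = TRUE) / pmax(colSums(obs), 1)
    d <- sweep(d, 2L, mu)
  }
  d[!obs] <- 0
  M <- crossprod(d) / pmax(counts, 1)
  M[counts == 0] <- NA_real_
  list(M = M, counts = counts)
}

# Per-SNP interval changes and masks for a panel (optionally jointly masked
# with the admixture-predicted changes).  A SNP contributes to interval i only
# if observed with n >= 2 at both bounding time points (and, when a trajectory
# is supplied, in every source with nonzero ancestry change in i).
panel_deltas <- function(panel, sources = NULL, trajectory = NULL,
                         warn_n1 = TRUE) {
  Tn <- ncol(panel$freq); K <- Tn - 1L
  if (K < 1L) stop_input("panel must have at least 2 time points")
  f <- panel$freq; n <- panel$n
  if (warn_n1 && any(n == 1))
    warning("entries with haploid sample size 1 are masked ",
            "(the 1/(n-1) noise terms need n >= 2)")
  ok_t <- n >= 2 & !is.na(f)
  d <- f[, -1L, drop = FALSE] - f[, -Tn, drop = FALSE]
  obs <- ok_t[, -Tn, drop = FALSE] & ok_t[, -1L, drop = FALSE]
  v <- f * (1 - f) / (n - 1)
  v[!ok_t] <- 0
  dA <- NULL; vsrc <- NULL; src_ok <- NULL
  if (!is.null(trajectory)) {
    if (is.null(sources))
      stop_input("a source panel is required when a trajectory is supplied")
    check_aligned(panel, sources)
    if (nrow(trajectory$alpha) != Tn)
      stop_input("trajectory has ", nrow(trajectory$alpha),
                 " time points but the panel has ", Tn)
    da <- trajectory$delta_alpha                       # K x R
    fs <- sources$freq; ns <- sources$n
    src_ok <- !is.na(fs) & ns >= 2
    need <- (abs(t(da)) > 1e-12) * 1                   # R x K
    bad <- ((!src_ok) %*% need) > 0                    # L x K
    obs <- obs & !bad
    fs0 <- fs; fs0[!src_ok] <- 0
    dA <- fs0 %*% t(da)
    vsrc <- fs * (1 - fs) / (ns - 1)
    vsrc[!src_ok] <- 0
  }
  d[!obs] <- NA_real_
  if (!is.null(dA)) dA[!obs] <- NA_real_
  list(d = d, obs = obs, v = v, dA = dA, vsrc = vsrc, K = K)
}

# Sampling-bias matrix entries for one set of rows.
ss_matrix_from <- function(v, obs, counts) {
  K <- ncol(obs)
  Ss <- matrix(0, K, K)
  vp <- v[, seq_len(K), drop = FALSE] + v[, seq_len(K) + 1L, drop = FALSE]
  diag(Ss) <- colSums(vp * obs) / pmax(diag(counts), 1)
  if (K >= 2) {
    for (i in seq_len(K - 1L)) {
      m <- obs[, i] & obs[, i + 1L]
      cnt <- sum(m)
      val <- if (cnt) -sum(v[m, i + 1L]) / cnt else NA_real_
      Ss[i, i + 1L] <- Ss[i + 1L, i] <- val
    }
  }
  Ss[counts == 0] <- NA_real_
  Ss
}

sa_matrix_from <- function(vsrc, obs, counts, delta_alpha) {
  K <- ncol(obs); R <- ncol(delta_alpha)
  SA <- matrix(0, K, K)
  for (r in seq_len(R)) {
    Wr <- crossprod(obs, obs * vsrc[, r])
    SA <- SA + tcrossprod(delta_alpha[, r]) * (Wr / pmax(counts, 1))
  }
  SA[counts == 0] <- NA_real_
  SA
}

# Per-window component matrices.
window_components <- function(panel, sources = NULL, trajectory = NULL,
                              centered = FALSE) {
  pd <- panel_deltas(panel, sources, trajectory)
  wid <- panel$window_id
  if (is.null(wid)) wid <- rep.int(1L, nrow(panel$freq))
  wids <- sort(unique(wid))
  per_window <- lapply(wids, function(w) {
    idx <- wid == w
    mR <- masked_cross_moment(pd$d[idx, , drop = FALSE], centered)
    Ss <- ss_matrix_from(pd$v[idx, , drop = FALSE],
                         pd$obs[idx, , drop = FALSE], mR$counts)
    if (!is.null(pd$dA)) {
      A <- masked_cross_moment(pd$dA[idx, , drop = FALSE], centered)$M
      SA <- sa_matrix_from(pd$vsrc[idx, , drop = FALSE],
                           pd$obs[idx, , drop = FALSE], mR$counts,
                           trajectory$delta_alpha)
    } else {
      A <- SA <- matrix(0, pd$K, pd$K)
    }
    list(R = mR$M, Ss = Ss, A_adm = A, SA = SA, counts = mR$counts,
         m = sum(idx))
  })
  names(per_window) <- as.character(wids)
  per_window
}

# Entrywise count-weighted aggregation of per-window matrices; identical to
# the pooled all-SNP computation.
aggregate_matrices <- function(per_window, field) {
  K <- nrow(per_window[[1]]$counts)
  num <- matrix(0, K, K); den <- matrix(0, K, K)
  for (w in per_window) {
    m <- w[[field]]
    ok <- !is.na(m) & w$counts > 0
    num[ok] <- num[ok] + m[ok] * w$counts[ok]
    den <- den + w$counts * ok
  }
  out <- num / pmax(den, 1)
  out[den == 0] <- NA_real_
  out
}

#' Raw temporal covariance matrix of allele-frequency change
#'
#' The K x K (K = T - 1) matrix `R[i, j]` = across-SNP moment of
#' `dp_i * dp_j`, where `dp_i` is the allele-frequency change over interval
#' i.  Computed per window and aggregated by per-entry SNP-count weighting.
#' This raw matrix still contains sampling noise (see
#' [sampling_bias_matrix()]) and any admixture contribution.
#'
#' @param panel a [freq_panel()] (windows assigned with [assign_windows()];
#'   a single window is assumed otherwise).
#' @param centered subtract per-window across-SNP mean changes (default
#'   FALSE; see package vignette).
#' @return K x K symmetric matrix.
#' @export
raw_cov_matrix <- function(panel, centered = FALSE) {
  pw <- window_components(panel, centered = centered)
  aggregate_matrices(pw, "R")
}

#' Expected sampling-bias matrix Ss for pseudohaploid panels
#'
#' Finite pseudohaploid samples inflate the apparent variance of
#' allele-frequency change, and the shared sample at the time point joining
#' two adjacent intervals induces a negative covariance between them.  For
#' haploid sample sizes n and sample frequencies p the per-SNP terms are
#' `p_i(1-p_i)/(n_i-1) + p_{i+1}(1-p_{i+1})/(n_{i+1}-1)` on the diagonal and
#' `-p_{i+1}(1-p_{i+1})/(n_{i+1}-1)` on the first off-diagonal
#' (`E[p(1-p)/(n-1)] = p0(1-p0)/n`, so these are unbiased for the sampling
#' noise); all other entries are structurally zero.  Averaged over SNPs with
#' the same masking and weighting as [raw_cov_matrix()].
#'
#' @inheritParams raw_cov_matrix
#' @return K x K matrix, nonzero only on the diagonal (>= 0) and first
#'   off-diagonal (<= 0).
#' @export
sampling_bias_matrix <- function(panel, centered = FALSE) {
  pw <- window_components(panel, centered = centered)
  aggregate_matrices(pw, "Ss")
}

#' Admixture-predicted per-SNP frequency changes
#'
#' The change in frequency expected from gene flow alone:
#' `dA p[l, i] = sum_r delta_alpha[i, r] * f[l, r]`, using the proxy sample
#' frequencies of the sources.  A SNP is masked in interval i if any source
#' with nonzero ancestry change is unobserved (or has n < 2) at that SNP.
#'
#' @param trajectory an [ancestry_traj()].
#' @param sources a [source_panel()].
#' @return L x K matrix (NA where masked).
#' @export
admixture_predicted_changes <- function(trajectory, sources) {
  da <- trajectory$delta_alpha
  fs <- sources$freq; ns <- sources$n
  src_ok <- !is.na(fs) & ns >= 2
  need <- (abs(t(da)) > 1e-12) * 1
  bad <- ((!src_ok) %*% need) > 0
  fs0 <- fs; fs0[!src_ok] <- 0
  dA <- fs0 %*% t(da)
  dA[bad] <- NA_real_
  colnames(dA) <- paste0("interval", seq_len(ncol(dA)))
  dA
}

#' Proxy-estimated admixture covariance matrix
#'
#' Across-SNP covariance matrix of the admixture-predicted changes
#' ([admixture_predicted_changes()]), i.e. the gene-flow contribution to the
#' temporal covariance of allele-frequency change, estimated with proxy
#' sample frequencies.  Its expectation is inflated by proxy sampling noise;
#' see [admixture_sampling_bias()].
#'
#' @inheritParams admixture_predicted_changes
#' @param panel optional aligned [freq_panel()]; supplies windows and the
#'   joint SNP masking used in the full pipeline.
#' @inheritParams raw_cov_matrix
#' @return K x K symmetric matrix.
#' @export
admixture_cov_matrix <- function(trajectory, sources, panel = NULL,
                                 centered = FALSE) {
  if (!is.null(panel)) {
    pw <- window_components(panel, sources, trajectory, centered)
    return(aggregate_matrices(pw, "A_adm"))
  }
  dA <- admixture_predicted_changes(trajectory, sources)
  masked_cross_moment(dA, centered)$M
}

#' Expected proxy-sampling bias SA of the admixture matrix
#'
#' The same proxy samples represent each source at every time interval, so
#' proxy sampling noise does not average out across intervals: it inflates
#' the proxy-estimated admixture matrix by
#' `SA[i, j] = mean_l sum_r delta_alpha[i, r] * delta_alpha[j, r] *
#' f[l, r](1 - f[l, r]) / (n[l, r] - 1)`.
#' Entries can be negative when the ancestry changes in intervals i and j
#' have opposite signs.  `E[proxy admixture matrix] = true matrix + SA`, so
#' the corrected admixture contribution is (proxy matrix - SA); the
#' Monte-Carlo oracle in the test suite pins this sign.
#'
#' @inheritParams admixture_cov_matrix
#' @return K x K symmetric matrix.
#' @export
admixture_sampling_bias <- function(trajectory, sources, panel = NULL) {
  if (!is.null(panel)) {
    pw <- window_components(panel, sources, trajectory)
    return(aggregate_matrices(pw, "SA"))
  }
  dA <- admixture_predicted_changes(trajectory, sources)
  obs <- !is.na(dA)
  counts <- crossprod(obs)
  vsrc <- sources$freq * (1 - sources$freq) / (sources$n - 1)
  vsrc[is.na(vsrc) | sources$n < 2] <- 0
  sa_matrix_from(vsrc, obs, counts, trajectory$delta_alpha)
}

# Noise-corrected across-SNP variance of the first time point's deviation
# from its ancestry-weighted source-proxy mixture: the standing deviation
# (accumulated drift plus any source misspecification) that later admixture
# pulses partially erase.  Feeds W_1 of drift_admixture_interaction().
standing_deviation_var <- function(panel, sources, trajectory) {
  a0 <- trajectory$alpha[1L, ]
  use_src <- abs(a0) > 1e-12
  ok <- panel$n[, 1L] >= 2 & !is.na(panel$freq[, 1L])
  for (r in which(use_src))
    ok <- ok & sources$n[, r] >= 2 & !is.na(sources$freq[, r])
  if (!any(ok)) return(0)
  p0 <- panel$freq[ok, 1L]
  fs <- sources$freq[ok, , drop = FALSE]
  fs[is.na(fs)] <- 0
  mix <- as.vector(fs %*% a0)
  noise <- p0 * (1 - p0) / (panel$n[ok, 1L] - 1)
  for (r in which(use_src))
    noise <- noise + a0[r]^2 * fs[, r] * (1 - fs[, r]) / (sources$n[ok, r] - 1)
  max(mean((p0 - mix)^2 - noise), 0)
}

# Infer per-interval pulse proportions from an ancestry trajectory under the
# one-gaining-source-per-interval assumption: a pulse of proportion m from
# source r dilutes every ancestry by (1-m) and adds m to source r, so
# m = delta_alpha_r / (1 - alpha_r) for the unique gaining source.
pulse_proportions <- function(trajectory, tol = 1e-8) {
  da <- trajectory$delta_alpha
  a <- trajectory$alpha
  K <- nrow(da)
  m <- numeric(K)
  for (i in seq_len(K)) {
    gain <- which(da[i, ] > tol)
    if (length(gain) > 1L)
      stop_input("intervals with more than one source gaining ancestry ",
                 "(interval ", i, ": ",
                 paste(colnames(da)[gain], collapse = ", "), "); the ",
                 "drift-admixture interaction assumes a single parental ",
                 "population contributes gene flow per interval")
    if (length(gain) == 1L)
      m[i] <- da[i, gain] / (1 - a[i, gain])
  }
  m
}

#' Expected drift-admixture interaction matrix D
#'
#' Drift in one interval is partially erased by later admixture: a pulse
#' replacing a fraction m of the population pulls the frequency back towards
#' the source, creating a negative covariance between earlier drift and the
#' pulse interval.  Write the focal frequency as the ancestry-weighted
#' source mixture plus an accumulated drift residual `eps` that each pulse
#' multiplies by (1 - m).  With `m_l` the pulse proportion in interval l
#' (inferred from the ancestry trajectory under the
#' one-contributing-source-per-interval assumption), the residual change in
#' interval l is (new drift) - `m_l * eps_l`, so the interaction between
#' intervals i < j is
#' `D[i, j] = -m_j * prod(1 - m_l, i < l < j) * (U_i - m_i (1 - m_i) W_i)`,
#' where `U_i` is the drift variance newly accrued (and surviving interval
#' i's own pulse) in interval i, and `W_i = Var(eps_i)` the standing drift
#' variance at the start of interval i.  Both are recovered recursively from
#' the plug-in corrected diagonal `diag_i = U_i + m_i^2 W_i` via
#' `W_{i+1} = (1 - m_i)^2 W_i + U_i`, starting from `W_1 = 0` (frequencies
#' and ancestry proportions are taken as exact at the first time point).
#' The diagonal of D is zero.
#'
#' @param trajectory an [ancestry_traj()].
#' @param drift_variances length-K nonnegative per-interval residual
#'   variances (corrected diagonal, e.g. `diag(R - Ss - (A_adm - SA))`).
#' @param standing_var0 standing deviation variance `W_1` of the first time
#'   point's frequencies around the ancestry-weighted source mixture
#'   (default 0; [corrected_cov_matrix()] estimates it from the data).
#' @return K x K symmetric matrix with zero diagonal.
#' @export
drift_admixture_interaction <- function(trajectory, drift_variances,
                                        standing_var0 = 0) {
  m <- pulse_proportions(trajectory)
  K <- length(m)
  if (length(drift_variances) != K)
    stop_input("drift_variances must have one entry per interval (", K, ")")
  V <- pmax(drift_variances, 0)
  # recover new-drift (U) and standing-drift (W) variances per interval
  U <- numeric(K); W <- numeric(K + 1L)
  W[1L] <- max(standing_var0, 0)
  for (i in seq_len(K)) {
    U[i] <- max(V[i] - m[i]^2 * W[i], 0)
    W[i + 1L] <- (1 - m[i])^2 * W[i] + U[i]
  }
  eff <- pmax(U - m * (1 - m) * W[seq_len(K)], 0)
  D <- matrix(0, K, K)
  if (K >= 2) {
    for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
      surv <- if (j - i >= 2) prod(1 - m[seq.int(i + 1L, j - 1L)]) else 1
      D[i, j] <- D[j, i] <- -m[j] * surv * eff[i]
    }
  }
  D
}

#' Corrected temporal covariance matrix and components
#'
#' Computes the raw covariance matrix R of allele-frequency change, the
#' pseudohaploid sampling-bias matrix Ss, the proxy-estimated admixture
#' matrix and its proxy-noise inflation SA, the drift-admixture interaction
#' D, and composes the corrected matrix
#' `C = (R - Ss) - (A_adm - SA) - D`,
#' whose expectation under neutral drift with fully modelled gene flow is
#' zero off the diagonal.  All components are retained, per window and
#' aggregated.
#'
#' @param panel a [freq_panel()]; windows are taken from `window_id`
#'   ([assign_windows()]) or the whole panel forms one window.
#' @param trajectory optional [ancestry_traj()]; omitting it (or supplying
#'   all-zero ancestry changes) reduces C to `R - Ss`.
#' @param sources [source_panel()], required with `trajectory`.
#' @param apply_D include the drift-admixture interaction (default TRUE);
#'   `FALSE` gives the no-interaction diagnostic variant.
#' @param centered see [raw_cov_matrix()].
#' @param sa_sign `"subtract"` (default) composes `-(A_adm - SA)`, the
#'   reading whose expectation removes the true admixture covariance (fixed
#'   by Monte-Carlo oracle); `"add"` composes `-(A_adm + SA)`.
#' @return An object of class `covariance_set`: matrices `R`, `Ss`, `A_adm`,
#'   `SA`, `D`, `C`; `per_window` component list; `weights` (per-window SNP
#'   counts); `drift_var` (plug-in per-interval drift variances); `het0`
#'   (per-time-point mean unbiased heterozygosity); `ages`; metadata.
#' @export
corrected_cov_matrix <- function(panel, trajectory = NULL, sources = NULL,
                                 apply_D = TRUE, centered = FALSE,
                                 sa_sign = c("subtract", "add")) {
  sa_sign <- match.arg(sa_sign)
  pw <- window_components(panel, sources, trajectory, centered)
  R <- aggregate_matrices(pw, "R")
  Ss <- aggregate_matrices(pw, "Ss")
  A_adm <- aggregate_matrices(pw, "A_adm")
  SA <- aggregate_matrices(pw, "SA")
  K <- nrow(R)
  adm_corr <- if (sa_sign == "subtract") A_adm - SA else A_adm + SA
  drift_var <- pmax(diag(R) - diag(Ss) - diag(adm_corr), 0)
  standing0 <- if (!is.null(trajectory))
    standing_deviation_var(panel, sources, trajectory) else 0
  D <- if (!is.null(trajectory) && apply_D)
    drift_admixture_interaction(trajectory, drift_var, standing0)
  else matrix(0, K, K)
  C <- (R - Ss) - adm_corr - D
  if (anyNA(C))
    warning("corrected matrix has missing entries (no usable SNPs); ",
            "downstream sums skip them")
  # unbiased mean heterozygosity per time point, over SNPs with n >= 2
  ok <- panel$n >= 2 & !is.na(panel$freq)
  hets <- panel$freq * (1 - panel$freq) * panel$n / (panel$n - 1)
  hets[!ok] <- NA_real_
  het0 <- colMeans(hets, na.rm = TRUE)
  ilabs <- paste0(panel$time_labels[-length(panel$time_labels)], "..",
                  panel$time_labels[-1L])
  out <- list(R = R, Ss = Ss, A_adm = A_adm, SA = SA, D = D, C = C,
              per_window = pw,
              weights = vapply(pw, function(w) w$m, numeric(1)),
              n_snps = nrow(panel$freq), K = K,
              interval_labels = ilabs, ages = panel$ages,
              time_labels = panel$time_labels, het0 = het0,
              drift_var = drift_var, standing_var0 = standing0,
              has_admixture = !is.null(trajectory),
              apply_D = apply_D, centered = centered, sa_sign = sa_sign)
  for (nm in c("R", "Ss", "A_adm", "SA", "D", "C"))
    dimnames(out[[nm]]) <- list(ilabs, ilabs)
  class(out) <- "covariance_set"
  out
}

#' @export
print.covariance_set <- function(x, digits = 4, ...) {
  cat(sprintf("covariance_set: %d intervals, %d SNPs in %d windows\n",
              x$K, x$n_snps, length(x$per_window)))
  cat(sprintf("  composition: C = (R - Ss) - (A_adm %s SA) - D%s; %s\n",
              if (x$sa_sign == "subtract") "-" else "+",
              if (x$apply_D) "" else "  [D not applied]",
              if (x$centered) "centered" else "uncentered"))
  cat("corrected matrix C:\n")
  print(round(x$C, digits))
  invisible(x)
}
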