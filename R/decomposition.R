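# Headline statistics: total variance, A(t), G(t), Gnc(t), drift fraction,
# temporal Ne.  Ratio statistics are computed per genomic window (numerator
# and denominator separately) and combined as ratios of SNP-count-weighted
# averages, which is also how the block bootstrap resamples them.

submat_sum <- function(M, t, offdiag_only = FALSE, what = "matrix") {
  sub <- M[seq_len(t), seq_len(t), drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub), arr.ind = TRUE)
    stop_numeric("missing ", what, " entries for t = ", t, ": ",
                 paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  if (offdiag_only) sum(sub) - sum(diag(sub)) else sum(sub)
}

#' Sampling-corrected total variance of allele-frequency change
#'
#' `Var(p_t - p_0)` estimated as the sum of all entries (variances plus
#' covariances) of the sampling-corrected matrix `R - Ss` restricted to the
#' first t intervals.  This is the empirical total, still containing any
#' admixture and selection contributions: it is the common denominator of the
#' A and G statistics.
#'
#' @param covset a `covariance_set` from [corrected_cov_matrix()].
#' @param t terminal time point, 1..K.
#' @return scalar.
#' @export
total_variance <- function(covset, t) {
  stopifnot(t >= 1, t <= covset$K)
  submat_sum(covset$R - covset$Ss, t, what = "R - Ss")
}

#' Proportion of allele-frequency variance attributable to gene flow
#'
#' `A(t)` = (sum of all entries of the proxy-noise-corrected admixture matrix
#' over the first t intervals) / `Var(p_t - p_0)`.  Values above 1 or
#' negative denominators are reported as-is (informative diagnostics on
#' noisy panels), not clipped.
#'
#' @inheritParams total_variance
#' @return scalar (NA with a warning if the denominator is not positive).
#' @export
stat_A <- function(covset, t) {
  if (!covset$has_admixture)
    stop_input("A(t) needs admixture matrices; supply a trajectory")
  num <- submat_sum(adm_corr_matrix(covset), t, what = "admixture")
  den <- total_variance(covset, t)
  ratio_or_flag(num, den, "A")
}

adm_corr_matrix <- function(covset) {
  if (covset$sa_sign == "subtract") covset$A_adm - covset$SA
  else covset$A_adm + covset$SA
}

ratio_or_flag <- function(num, den, name) {
  if (!is.finite(den) || den <= 0) {
    warning(name, "(t) undefined: total variance denominator is ",
            format(den))
    return(NA_real_)
  }
  num / den
}

#' Proportion of variance attributable to linked selection
#'
#' `G(t)` is the sum of off-diagonal (between-interval) covariances of the
#' fully corrected matrix C over the first t intervals, divided by
#' `Var(p_t - p_0)`.  Drift generates no between-interval covariance, so
#' after removing sampling noise, the admixture contribution, and the
#' drift-admixture interaction, residual covariance is the signature of
#' sustained directional change — linked selection.  `stat_Gnc` is the same
#' ratio without any admixture subtraction ("not controlling" variant).
#'
#' @inheritParams total_variance
#' @return scalar; requires `t >= 2` (no off-diagonal terms otherwise).
#' @export
stat_G <- function(covset, t) {
  stopifnot(t >= 2)
  num <- submat_sum(covset$C, t, offdiag_only = TRUE, what = "C")
  if (!covset$has_admixture && covset$apply_D) {
    # C already equals R - Ss here; nothing further to subtract
  }
  ratio_or_flag(num, total_variance(covset, t), "G")
}

#' @rdname stat_G
#' @export
stat_Gnc <- function(covset, t) {
  stopifnot(t >= 2)
  num <- submat_sum(covset$R - covset$Ss, t, offdiag_only = TRUE,
                    what = "R - Ss")
  ratio_or_flag(num, total_variance(covset, t), "Gnc")
}

#' Residual drift fraction
#'
#' `1 - A(t) - G(t)`: the proportion of total temporal variance left to
#' drift-like change (within-interval variance not explained by modelled
#' gene flow).
#'
#' @inheritParams total_variance
#' @return scalar.
#' @export
drift_fraction <- function(covset, t) {
  1 - stat_A(covset, t) - stat_G(covset, t)
}

#' Temporal effective population size from residual drift variance
#'
#' Inverts the Wright-Fisher drift-variance accumulation
#' `Var = het0 * (1 - (1 - 1/(2N))^t)` in closed form:
#' `2N = 1 / (1 - (1 - Var/het0)^(1/t))`.
#'
#' @param residual_variance drift variance accrued over the interval; must
#'   lie in (0, het0) for a defined estimate.
#' @param het0 mean initial heterozygosity `p0 * (1 - p0)` across SNPs.
#' @param t_generations number of generations elapsed (>= 1).
#' @return The diploid effective size `2N` (NA with a warning outside the
#'   domain).
#' @export
estimate_Ne <- function(residual_variance, het0, t_generations) {
  len <- max(length(residual_variance), length(het0), length(t_generations))
  residual_variance <- rep_len(residual_variance, len)
  het0 <- rep_len(het0, len)
  t_generations <- rep_len(t_generations, len)
  if (any(t_generations < 1, na.rm = TRUE))
    stop_input("t_generations must be >= 1")
  out <- rep(NA_real_, len)
  ok <- is.finite(residual_variance) & is.finite(het0) &
    residual_variance > 0 & residual_variance < het0
  if (any(!ok))
    warning("Ne undefined for residual variance outside (0, het0); flagged NA")
  out[ok] <- 1 / (1 - (1 - residual_variance[ok] / het0[ok])^
                    (1 / t_generations[ok]))
  out
}

#' Convert an age gap to generations
#'
#' @param ages numeric ages (oldest first).
#' @param age_unit `"generations"` or `"years"`.
#' @param generation_time years per generation when `age_unit = "years"`
#'   (default 30).
#' @return per-interval generation counts (length `length(ages) - 1`).
#' @export
generations_between <- function(ages, age_unit = c("generations", "years"),
                                generation_time = 30) {
  age_unit <- match.arg(age_unit)
  gaps <- -diff(ages)
  if (age_unit == "years") gaps <- gaps / generation_time
  gaps
}

#' Full variance decomposition with bootstrap confidence intervals
#'
#' Runs the covariance pipeline ([corrected_cov_matrix()]) and computes, for
#' every terminal time point t, the total variance, A(t), G(t), Gnc(t) and
#' the residual drift fraction, each with a block-bootstrap pivot CI over
#' genomic windows, plus per-interval residual drift variances and temporal
#' effective population sizes.
#'
#' @inheritParams corrected_cov_matrix
#' @param boot a [bootstrap_spec()]; `n_boot = 0` suppresses CIs.
#' @param age_unit,generation_time see [generations_between()].
#' @return An object of class `decomposition_result` with fields `stats`
#'   (tidy data.frame: statistic, t, value, ci_low, ci_high), `ne`
#'   (per-interval data.frame), and `covset`.
#' @export
decompose_variance <- function(panel, trajectory = NULL, sources = NULL,
                               apply_D = TRUE, centered = FALSE,
                               sa_sign = c("subtract", "add"),
                               boot = bootstrap_spec(),
                               age_unit = c("generations", "years"),
                               generation_time = 30) {
  sa_sign <- match.arg(sa_sign)
  age_unit <- match.arg(age_unit)
  covset <- corrected_cov_matrix(panel, trajectory, sources, apply_D,
                                 centered, sa_sign)
  K <- covset$K
  pw <- covset$per_window
  weights <- covset$weights
  sgn <- if (sa_sign == "subtract") -1 else 1
  Doff <- covset$D
  # per-window sums for each statistic; NA entries are skipped (warned once
  # by corrected_cov_matrix upstream)
  wsum <- function(w, t, M, offdiag = FALSE) {
    sub <- M[seq_len(t), seq_len(t), drop = FALSE]
    if (offdiag) diag(sub) <- 0
    sum(sub, na.rm = TRUE)
  }
  rows <- list(); ne_rows <- list()
  do_ci <- !is.null(boot) && boot$n_boot > 0
  for (t in seq_len(K)) {
    den_w <- vapply(pw, function(w) wsum(w, t, w$R - w$Ss), numeric(1))
    numA_w <- if (covset$has_admixture)
      vapply(pw, function(w) wsum(w, t, w$A_adm + sgn * w$SA), numeric(1))
    else NULL
    gnc_w <- vapply(pw, function(w) wsum(w, t, w$R - w$Ss, offdiag = TRUE),
                    numeric(1))
    d_off <- sum(Doff[seq_len(t), seq_len(t)])
    g_w <- if (covset$has_admixture)
      vapply(pw, function(w)
        wsum(w, t, (w$R - w$Ss) - (w$A_adm + sgn * w$SA), offdiag = TRUE),
        numeric(1)) - d_off
    else gnc_w - d_off
    add_stat <- function(name, num, den = NULL) {
      bb <- block_bootstrap(num, den, weights, boot)
      rows[[length(rows) + 1L]] <<- data.frame(
        statistic = name, t = t, time = covset$time_labels[t + 1L],
        value = bb$estimate,
        ci_low = if (do_ci) bb$ci[1] else NA_real_,
        ci_high = if (do_ci) bb$ci[2] else NA_real_,
        stringsAsFactors = FALSE)
    }
    add_stat("total_var", den_w)
    if (covset$has_admixture) add_stat("A", numA_w, den_w)
    if (t >= 2) {
      add_stat("Gnc", gnc_w, den_w)
      add_stat("G", g_w, den_w)
      if (covset$has_admixture)
        add_stat("drift_frac", den_w - numA_w - g_w, den_w)
    }
  }
  gens <- generations_between(covset$ages, age_unit, generation_time)
  resid <- covset$drift_var
  het_start <- covset$het0[seq_len(K)]
  ne <- data.frame(interval = covset$interval_labels,
                   residual_var = resid, het0 = het_start,
                   generations = gens,
                   Ne2N = ifelse(gens >= 1, suppressWarnings(
                     estimate_Ne(resid, het_start, pmax(gens, 1))),
                     NA_real_),
                   stringsAsFactors = FALSE)
  structure(list(stats = do.call(rbind, rows), ne = ne, covset = covset,
                 boot = boot),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, digits = 4, ...) {
  cat("decomposition_result\n")
  df <- x$stats
  df$value <- signif(df$value, digits)
  if (!all(is.na(df$ci_low))) {
    df$ci_low <- signif(df$ci_low, digits)
    df$ci_high <- signif(df$ci_high, digits)
  } else df$ci_low <- df$ci_high <- NULL
  print(df, row.names = FALSE)
  cat("\nper-interval residual drift and temporal Ne:\n")
  ne <- x$ne; ne$residual_var <- signif(ne$residual_var, digits)
  ne$Ne2N <- signif(ne$Ne2N, digits)
  print(ne, row.names = FALSE)
  invisible(x)
}
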