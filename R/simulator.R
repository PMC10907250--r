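# Forward Wright-Fisher simulation engine: multiple populations, pulse
# admixture, pseudohaploid sampling, optional selection overlays, with exact
# ancestry bookkeeping and a ground-truth variance decomposition.
#
# Loci are simulated unlinked (independent WF per locus).  Linked-selection
# effects are produced by selection overlays acting on a separate set of
# trait/deleterious loci; analyzed neutral loci pick up their sustained
# change through a hitchhiking-correlation parameter (linkage_tightness)
# that couples each neutral locus to a selected partner locus.  This is a
# desk-scale surrogate for chromosome-scale linked simulation: it preserves
# the signs and trends of the temporal-covariance signal, not its absolute
# magnitude.

#' Selection overlay specification
#'
#' @param mode `"none"`, `"gss"` (Gaussian stabilizing selection with a
#'   moving optimum), `"directional"`, or `"bgs"` (recurrent deleterious
#'   mutation).
#' @param n_traits number of independent traits under GSS (default 3).
#' @param effect_size absolute per-allele effect; each trait locus gets a
#'   random sign (default 0.01).
#' @param Vs variance of the Gaussian fitness landscape (default 1).
#' @param shift_sd optimum displacement, in trait SDs at shift start
#'   (default 3).
#' @param shift_start_gen generation BP at which the optimum starts moving
#'   linearly towards its final value at generation 0 (default 140).
#' @param s selection coefficient: directional (default 0.05) or
#'   deleterious for BGS (default -0.1).
#' @param U deleterious mutation rate per haploid genome per generation for
#'   BGS (default 1).
#' @param n_selected number of selected loci (default 300; they are kept out
#'   of the analysis panel).
#' @param linkage_tightness hitchhiking coupling in \[0, 1\] between each
#'   neutral locus and its selected partner (default 0.5).
#' @return An object of class `selection_overlay`.
#' @export
selection_overlay <- function(mode = c("none", "gss", "directional", "bgs"),
                              n_traits = 3, effect_size = 0.01, Vs = 1,
                              shift_sd = 3, shift_start_gen = 140,
                              s = NULL, U = 1, n_selected = 300,
                              linkage_tightness = 0.5) {
  mode <- match.arg(mode)
  if (is.null(s)) s <- if (mode == "bgs") -0.1 else 0.05
  if (mode == "bgs" && s >= 0) stop_input("BGS needs a negative s")
  stopifnot(effect_size >= 0, Vs > 0, U > 0, n_selected >= 0,
            linkage_tightness >= 0, linkage_tightness <= 1)
  structure(list(mode = mode, n_traits = n_traits,
                 effect_size = effect_size, Vs = Vs, shift_sd = shift_sd,
                 shift_start_gen = shift_start_gen, s = s, U = U,
                 n_selected = as.integer(n_selected),
                 linkage_tightness = linkage_tightness),
            class = "selection_overlay")
}

#' Simulation configuration
#'
#' Defaults reproduce a two-source pulse-admixture scenario: a focal
#' population of 10,000 diploids founded from source 1 at 200 generations
#' BP, receiving pulses of proportion 0.1 from source 2 every 20 generations
#' from 150 to 10 generations BP, sampled pseudohaploid (30 haploid calls)
#' 10 generations before and after the pulse epochs, with source proxies (30
#' haploid calls each) sampled at the founding generation.
#'
#' @param n_loci number of unlinked analysis loci (default 10000).
#' @param N_focal diploid size of the focal population (default 10000;
#'   `Inf` disables drift).
#' @param N_source diploid size(s) of the sources (recycled; default
#'   `N_focal`).
#' @param n_sources number of source populations (default 2).
#' @param founder_source source the focal population is founded from
#'   (default 1).
#' @param start_gen founding generation BP (default 200).
#' @param pulse_gens,pulse_sources,pulse_m pulse schedule: generation BP,
#'   source index, admixture proportion in (0,1) (recycled).
#' @param sample_gens generations BP at which the focal population is
#'   sampled (default `c(160,140,120,100,60,40,20,0)`).
#' @param sample_n haploid pseudohaploid sample size per time point
#'   (default 30).
#' @param proxy_gen generation BP at which source proxies are sampled
#'   (default `start_gen`).
#' @param proxy_n haploid proxy sample size (default 30).
#' @param proxy_drift_gen extra generations of private drift between each
#'   true source and its proxy (default 0; emulates source
#'   misspecification).
#' @param source_drift do source populations drift (default FALSE, matching
#'   the constant-source model assumption; TRUE emulates real drifting
#'   sources whose proxies become misspecified over time).
#' @param init_freq `"uniform"` (default, Uniform(0.05, 0.95)) or `"beta"`
#'   (SFS-shaped Beta(`beta_shape`, `beta_shape`) truncated to the same
#'   range).
#' @param beta_shape shape for `init_freq = "beta"` (default 0.2).
#' @param missing_rate per-call missingness probability in sampling
#'   (default 0).
#' @param overlay a [selection_overlay()] (default none).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10000, N_focal = 10000, N_source = N_focal,
                       n_sources = 2, founder_source = 1, start_gen = 200,
                       pulse_gens = c(150, 130, 110, 50, 30, 10),
                       pulse_sources = 2, pulse_m = 0.1,
                       sample_gens = c(160, 140, 120, 100, 60, 40, 20, 0),
                       sample_n = 30, proxy_gen = start_gen, proxy_n = 30,
                       proxy_drift_gen = 0, source_drift = FALSE,
                       init_freq = c("uniform", "beta"), beta_shape = 0.2,
                       missing_rate = 0, overlay = selection_overlay("none")) {
  init_freq <- match.arg(init_freq)
  np <- length(pulse_gens)
  pulse_sources <- rep_len(pulse_sources, np)
  pulse_m <- rep_len(pulse_m, np)
  if (np && (any(pulse_m <= 0) || any(pulse_m >= 1)))
    stop_input("pulse proportions must lie in (0, 1)")
  if (np && (any(pulse_gens <= 0) || any(pulse_gens >= start_gen)))
    stop_input("pulse generations must lie strictly inside (0, start_gen)")
  if (np && any(pulse_sources < 1 | pulse_sources > n_sources))
    stop_input("pulse source index out of range")
  if (any(sample_gens < 0) || any(sample_gens > start_gen))
    stop_input("sample generations must lie in [0, start_gen]")
  if (is.unsorted(rev(sample_gens), strictly = TRUE))
    stop_input("sample_gens must be strictly decreasing (oldest first)")
  if (proxy_gen < 0 || proxy_gen > start_gen)
    stop_input("proxy_gen must lie in [0, start_gen]")
  stopifnot(n_loci >= 1, N_focal >= 1, all(N_source >= 1), sample_n >= 2,
            proxy_n >= 2, missing_rate >= 0, missing_rate < 1)
  structure(list(n_loci = as.integer(n_loci), N_focal = N_focal,
                 N_source = rep_len(N_source, n_sources),
                 n_sources = as.integer(n_sources),
                 founder_source = as.integer(founder_source),
                 start_gen = as.integer(start_gen),
                 pulse_gens = as.integer(pulse_gens),
                 pulse_sources = as.integer(pulse_sources),
                 pulse_m = pulse_m, sample_gens = as.integer(sample_gens),
                 sample_n = as.integer(sample_n),
                 proxy_gen = as.integer(proxy_gen),
                 proxy_n = as.integer(proxy_n),
                 proxy_drift_gen = as.integer(proxy_drift_gen),
                 source_drift = source_drift, init_freq = init_freq,
                 beta_shape = beta_shape, missing_rate = missing_rate,
                 overlay = overlay),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d loci, focal N=%s, %d sources, %d pulses, %d sample times\n",
              x$n_loci, format(x$N_focal), x$n_sources, length(x$pulse_gens),
              length(x$sample_gens)))
  cat(sprintf("  overlay: %s\n", x$overlay$mode))
  invisible(x)
}

wf_drift <- function(p, N) {
  if (!is.finite(N)) return(p)
  stats::rbinom(length(p), 2 * N, p) / (2 * N)
}

draw_init_freq <- function(config, n) {
  lo <- 0.05; hi <- 0.95
  if (config$init_freq == "uniform") stats::runif(n, lo, hi)
  else {
    p <- stats::rbeta(n, config$beta_shape, config$beta_shape)
    pmin(pmax(p, lo), hi)
  }
}

# One generation of deterministic selection change on the selected loci;
# returns the per-locus change (applied by the caller).
selection_change <- function(ps, ov, gen, state) {
  if (ov$mode == "directional") {
    return(ov$s * ps * (1 - ps))
  }
  if (ov$mode == "bgs") {
    # purifying selection plus recurrent deleterious input
    mu <- ov$U / ov$n_selected
    dsel <- ov$s * ps * (1 - ps) / (1 + ov$s * ps)
    return(dsel + mu * (1 - ps))
  }
  # gss: three independent traits; optimum moves linearly after
  # shift_start_gen; directional response a*p(1-p)*(opt - zbar)/(Vs + Vg)
  d <- numeric(length(ps))
  for (k in seq_len(ov$n_traits)) {
    idx <- state$trait == k
    a <- state$effect[idx]
    zbar <- sum(2 * a * ps[idx])
    Vg <- sum(2 * a^2 * ps[idx] * (1 - ps[idx]))
    if (gen == ov$shift_start_gen && is.na(state$sd0[k]))
      state$sd0[k] <- sqrt(max(Vg, 1e-12))
    opt <- if (gen > ov$shift_start_gen || is.na(state$sd0[k])) 0
    else ov$shift_sd * state$sd0[k] *
      (ov$shift_start_gen - gen) / ov$shift_start_gen
    d[idx] <- a * ps[idx] * (1 - ps[idx]) * (opt - zbar) / (ov$Vs + Vg)
  }
  d
}

#' Forward Wright-Fisher simulation with pulse admixture
#'
#' Simulates `n_sources` source populations and one focal population, locus
#' by locus (unlinked), generation by generation: binomial drift, admixture
#' pulses `p <- (1-m) p + m p_source` with exact ancestry bookkeeping
#' `alpha <- (1-m) alpha + m e_r`, pseudohaploid sampling at the configured
#' times, and a single proxy sample per source.  When the configuration
#' carries a selection overlay, the selected loci evolve under it and each
#' neutral locus receives a hitchhiking share of its partner's
#' selection-driven change; only neutral loci enter the returned panel.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (full determinism under a fixed seed).
#' @param keep_trajectories record the focal neutral-frequency matrix at
#'   every generation (needed by [interval_sweep()]).
#' @return An object of class `sim_result`: `panel` ([freq_panel()]),
#'   `sources` ([source_panel()]), `trajectory` (exact [ancestry_traj()]),
#'   `truth` (ground-truth decomposition from the true frequencies: matrices
#'   `A_true` (realized pulse changes), `A_model` (ancestry changes applied
#'   to true source frequencies — the estimand of the A statistic),
#'   `D_true`, `cross`, `total`, curves `A`, `total_var`),
#'   `true_freq` (L x T true focal frequencies at sample times),
#'   `gen_traj` (if requested), `config`, `seed`.
#' @export
simulate_panel <- function(config, seed = NULL, keep_trajectories = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ov <- config$overlay
  L <- config$n_loci
  R <- config$n_sources
  nsel <- if (ov$mode == "none") 0L else ov$n_selected
  # initial frequencies; selected loci appended after the neutral block
  p_src <- matrix(draw_init_freq(config, L * R), L, R)
  psel_src <- if (nsel) matrix(draw_init_freq(config, nsel * R), nsel, R)
  sel_state <- NULL
  if (nsel) {
    sel_state <- new.env()
    sel_state$trait <- rep_len(seq_len(max(ov$n_traits, 1L)), nsel)
    sel_state$effect <- sample(c(-1, 1), nsel, TRUE) * ov$effect_size
    sel_state$sd0 <- rep(NA_real_, max(ov$n_traits, 1L))
    if (ov$mode == "bgs") psel_src[] <- 0.05   # deleterious start rare
    partner <- sample.int(nsel, L, replace = TRUE)
    hh_sign <- sample(c(-1, 1), L, TRUE)
  }
  fs <- config$founder_source
  p_foc <- p_src[, fs]
  psel_foc <- if (nsel) psel_src[, fs]
  alpha <- numeric(R); alpha[fs] <- 1
  Tn <- length(config$sample_gens)
  K <- Tn - 1L
  sfreq <- matrix(NA_real_, L, Tn)     # sampled panel
  sn <- matrix(0L, L, Tn)
  tfreq <- matrix(NA_real_, L, Tn)     # true focal frequencies
  alpha_t <- matrix(NA_real_, Tn, R)
  adm_change <- matrix(0, L, K)        # truth: admixture-driven change
  proxy_freq <- proxy_n <- src_true <- NULL
  gen_traj <- if (keep_trajectories)
    matrix(NA_real_, L, config$start_gen + 1L)
  cur_interval <- 0L                   # 0 = before first sample
  for (g in seq.int(config$start_gen, 0L)) {
    if (keep_trajectories) gen_traj[, config$start_gen - g + 1L] <- p_foc
    # sampling at this generation
    si <- match(g, config$sample_gens)
    if (!is.na(si)) {
      nhap <- if (config$missing_rate > 0)
        stats::rbinom(L, config$sample_n, 1 - config$missing_rate)
      else rep.int(config$sample_n, L)
      x <- stats::rbinom(L, nhap, p_foc)
      sfreq[, si] <- ifelse(nhap > 0, x / pmax(nhap, 1L), NA_real_)
      sn[, si] <- nhap
      tfreq[, si] <- p_foc
      alpha_t[si, ] <- alpha
      cur_interval <- si
    }
    if (g == config$proxy_gen) {
      pp <- p_src
      if (config$proxy_drift_gen > 0)
        for (r in seq_len(R)) for (dg in seq_len(config$proxy_drift_gen))
          pp[, r] <- wf_drift(pp[, r], config$N_source[r])
      src_true <- pp
      proxy_n <- matrix(config$proxy_n, L, R)
      proxy_freq <- matrix(stats::rbinom(L * R, config$proxy_n, pp),
                           L, R) / config$proxy_n
    }
    # pulse(s) scheduled at this generation
    pi_ <- which(config$pulse_gens == g)
    for (k in pi_) {
      m <- config$pulse_m[k]; r <- config$pulse_sources[k]
      dadm <- m * (p_src[, r] - p_foc)
      p_foc <- p_foc + dadm
      if (nsel) psel_foc <- psel_foc + m * (psel_src[, r] - psel_foc)
      alpha <- (1 - m) * alpha
      alpha[r] <- alpha[r] + m
      stopifnot(abs(sum(alpha) - 1) < 1e-12)
      if (cur_interval >= 1L && cur_interval <= K)
        adm_change[, cur_interval] <- adm_change[, cur_interval] + dadm
    }
    if (g > 0L) {
      # selection (deterministic part), hitchhiking, then drift
      if (nsel) {
        dsel <- selection_change(psel_foc, ov, g, sel_state)
        psel_foc <- pmin(pmax(psel_foc + dsel, 0), 1)
        het_sel <- psel_foc * (1 - psel_foc)
        het_neu <- p_foc * (1 - p_foc)
        hb <- het_sel[partner]
        scale <- ifelse(hb > 1e-8, sqrt(het_neu / hb), 0)
        p_foc <- pmin(pmax(
          p_foc + ov$linkage_tightness * hh_sign * dsel[partner] * scale,
          0), 1)
      }
      p_foc <- wf_drift(p_foc, config$N_focal)
      if (nsel) psel_foc <- wf_drift(psel_foc, config$N_focal)
      if (config$source_drift) {
        for (r in seq_len(R)) {
          p_src[, r] <- wf_drift(p_src[, r], config$N_source[r])
          if (nsel) psel_src[, r] <- wf_drift(psel_src[, r],
                                              config$N_source[r])
        }
      }
    }
  }
  stopifnot(all(abs(rowSums(alpha_t) - 1) < 1e-12))
  if (is.null(proxy_freq))
    stop_input("proxy_gen was never reached; check the schedule")
  labs <- paste0("g", config$sample_gens)
  panel <- freq_panel(paste0("snp", seq_len(L)), rep("1", L), seq_len(L),
                      sfreq, sn, time_labels = labs,
                      ages = config$sample_gens)
  src_labels <- paste0("src", seq_len(R))
  sources <- source_panel(panel$snp_id, proxy_freq, proxy_n, src_labels)
  trajectory <- ancestry_traj(alpha_t, time_labels = labs,
                              ages = config$sample_gens,
                              source_labels = src_labels, tol = 1e-9)
  # ground-truth decomposition from true frequencies
  tot_change <- tfreq[, -1L, drop = FALSE] - tfreq[, -Tn, drop = FALSE]
  drift_change <- tot_change - adm_change
  A_true <- crossprod(adm_change) / L
  D_true <- crossprod(drift_change) / L
  cross <- crossprod(adm_change, drift_change) / L
  total <- crossprod(tot_change) / L
  # model-based admixture change (the estimand of the A statistic): ancestry
  # changes applied to the true source frequencies at the proxy time
  da_true <- alpha_t[-1L, , drop = FALSE] - alpha_t[-Tn, , drop = FALSE]
  A_model <- crossprod(src_true %*% t(da_true)) / L
  truth_A <- vapply(seq_len(K), function(t)
    sum(A_model[seq_len(t), seq_len(t)]) /
      sum(total[seq_len(t), seq_len(t)]), numeric(1))
  truth <- list(A_true = A_true, A_model = A_model, D_true = D_true,
                cross = cross, total = total, A = truth_A,
                total_var = vapply(seq_len(K), function(t)
                  sum(total[seq_len(t), seq_len(t)]), numeric(1)))
  structure(list(panel = panel, sources = sources, trajectory = trajectory,
                 truth = truth, true_freq = tfreq,
                 gen_traj = if (keep_trajectories) gen_traj,
                 config = config, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result\n")
  print(x$panel)
  print(x$trajectory)
  invisible(x)
}

#' Simulate with a selection overlay
#'
#' Convenience wrapper: attaches `overlay` to the configuration and runs
#' [simulate_panel()].  Only neutral loci appear in the returned panel;
#' their hitchhiking partners evolve under the overlay.
#'
#' @inheritParams simulate_panel
#' @param overlay a [selection_overlay()].
#' @return A `sim_result`.
#' @export
simulate_selection <- function(config, overlay, seed = NULL,
                               keep_trajectories = FALSE) {
  config$overlay <- overlay
  if (overlay$mode != "none" && overlay$n_selected == 0) {
    warning("selection overlay with zero selected loci; running neutral")
    config$overlay <- selection_overlay("none")
  }
  simulate_panel(config, seed, keep_trajectories)
}

#' Covariance/variance sums across sampling intervals and linkage tightness
#'
#' Re-analyzes simulated true-frequency trajectories at several sampling
#' intervals (generations between analysis time points) and across
#' hitchhiking-coupling levels, returning the summed between-interval
#' covariance and summed variance for each combination: sustained selection
#' shifts signal from covariance to within-interval variance as the
#' sampling interval grows, and both grow with tighter linkage.
#'
#' @param config a [sim_config()] (its overlay is used as-is for each run;
#'   linkage tightness is overridden per level).
#' @param sampling_intervals analysis time steps in generations
#'   (default `c(2, 5, 10, 15, 20)`).
#' @param linkage_levels hitchhiking-coupling levels to sweep
#'   (default the config's own).
#' @param span generations BP at which the analysis starts (default
#'   `overlay$shift_start_gen`, capped at `start_gen - 1`).
#' @param n_reps replicates per level (default 10).
#' @param seed integer seed.
#' @return data.frame: linkage, interval, replicate, sum_cov, sum_var.
#' @export
interval_sweep <- function(config, sampling_intervals = c(2, 5, 10, 15, 20),
                           linkage_levels = NULL, span = NULL, n_reps = 10,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(linkage_levels))
    linkage_levels <- config$overlay$linkage_tightness
  if (is.null(span))
    span <- min(config$overlay$shift_start_gen, config$start_gen - 1L)
  sampling_intervals <- sampling_intervals[sampling_intervals <= span]
  if (!length(sampling_intervals))
    stop_input("all sampling intervals exceed the simulated span")
  rows <- list()
  for (rho in linkage_levels) {
    cfg <- config
    cfg$overlay$linkage_tightness <- rho
    for (rep_ in seq_len(n_reps)) {
      sim <- simulate_panel(cfg, keep_trajectories = TRUE)
      for (iv in sampling_intervals) {
        # identical total span for every interval length: anchor at the
        # present and keep a shorter oldest sub-interval when iv does not
        # divide the span evenly
        gens <- rev(unique(c(seq(0, span, by = iv), span)))
        if (length(gens) < 3) {
          warning("interval ", iv, " leaves fewer than 2 analysis intervals; skipped")
          next
        }
        cols <- cfg$start_gen - gens + 1L
        fr <- sim$gen_traj[, cols, drop = FALSE]
        d <- fr[, -1L, drop = FALSE] - fr[, -ncol(fr), drop = FALSE]
        M <- crossprod(d) / nrow(d)
        rows[[length(rows) + 1L]] <- data.frame(
          linkage = rho, interval = iv, replicate = rep_,
          sum_cov = sum(M) - sum(diag(M)), sum_var = sum(diag(M)))
      }
    }
  }
  do.call(rbind, rows)
}
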