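# Block bootstrap over genomic windows, pivot confidence intervals, and
# annotation quantile binning.

#' Bootstrap specification
#'
#' @param n_boot number of bootstrap resamples (default 10^4; at least 100
#'   for CI output, `0` disables CIs).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed recorded in outputs; `NULL` leaves the RNG state
#'   alone.
#' @param subsample_fraction fraction of windows drawn per replicate
#'   (default 1).  Use `1/k` to make a genome-wide CI width comparable to
#'   k-quantile-bin CIs.
#' @return An object of class `bootstrap_spec` (method tag `"pivot"`).
#' @export
bootstrap_spec <- function(n_boot = 1e4, conf = 0.95, seed = NULL,
                           subsample_fraction = 1) {
  if (n_boot > 0 && n_boot < 100)
    stop_input("n_boot must be 0 (no CIs) or >= 100")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop_input("subsample_fraction must be in (0, 1]")
  structure(list(n_boot = as.integer(n_boot), conf = conf, method = "pivot",
                 seed = seed, subsample_fraction = subsample_fraction),
            class = "bootstrap_spec")
}

#' Block bootstrap of a weighted (ratio) statistic over windows
#'
#' The point estimate is the ratio of SNP-count-weighted averages:
#' `sum(w * num) / sum(w)` over `sum(w * den) / sum(w)` (non-ratio statistics
#' pass `den = NULL`, i.e. denominator 1).  Each replicate resamples windows
#' with replacement (uniformly — weights enter only in the statistic) and
#' recomputes the weighted ratio; the pivot CI is
#' `[2*est - q_{1-a/2}, 2*est - q_{a/2}]` of the replicate distribution.
#'
#' @param numerators per-window numerator sums.
#' @param denominators per-window denominator sums, or `NULL` for 1.
#' @param weights per-window SNP counts.
#' @param spec a [bootstrap_spec()].
#' @return list with `estimate`, `ci` (length 2, NA when `n_boot = 0`),
#'   `replicates`, `n_redrawn` (replicates redrawn for zero total weight),
#'   `spec`.
#' @export
block_bootstrap <- function(numerators, denominators = NULL, weights,
                            spec = bootstrap_spec()) {
  W <- length(numerators)
  if (W < 1) stop_input("at least one window is required")
  if (is.null(denominators)) denominators <- rep(1, W)
  if (length(denominators) != W || length(weights) != W)
    stop_input("numerators, denominators and weights must align per window")
  wstat <- function(idx) {
    sw <- sum(weights[idx])
    if (sw == 0) return(NA_real_)
    num <- sum(weights[idx] * numerators[idx]) / sw
    den <- sum(weights[idx] * denominators[idx]) / sw
    num / den
  }
  est <- wstat(seq_len(W))
  if (is.null(spec) || spec$n_boot == 0)
    return(list(estimate = est, ci = c(NA_real_, NA_real_),
                replicates = numeric(0), n_redrawn = 0L, spec = spec))
  if (W < 2) {
    warning("fewer than 2 windows: CI omitted")
    return(list(estimate = est, ci = c(NA_real_, NA_real_),
                replicates = numeric(0), n_redrawn = 0L, spec = spec))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ndraw <- max(1L, round(spec$subsample_fraction * W))
  # all replicates drawn at once; zero-total-weight replicates redrawn
  draw_reps <- function(B) {
    idx <- matrix(sample.int(W, ndraw * B, replace = TRUE), nrow = B)
    sw <- matrix(weights[idx], nrow = B)
    tot_w <- rowSums(sw)
    num <- rowSums(sw * matrix(numerators[idx], nrow = B)) / tot_w
    den <- rowSums(sw * matrix(denominators[idx], nrow = B)) / tot_w
    ifelse(tot_w > 0, num / den, NA_real_)
  }
  reps <- draw_reps(spec$n_boot)
  n_redrawn <- 0L
  while (anyNA(reps)) {
    bad <- which(is.na(reps))
    n_redrawn <- n_redrawn + length(bad)
    if (n_redrawn > 100L * spec$n_boot)
      stop_numeric("bootstrap cannot draw replicates with nonzero weight")
    reps[bad] <- draw_reps(length(bad))
  }
  if (n_redrawn > 0)
    warning(n_redrawn, " bootstrap replicate(s) redrawn (zero total weight)")
  a <- (1 - spec$conf) / 2
  q <- stats::quantile(reps, c(1 - a, a), names = FALSE, type = 7)
  list(estimate = est, ci = c(2 * est - q[1], 2 * est - q[2]),
       replicates = reps, n_redrawn = n_redrawn, spec = spec)
}

#' Quantile bins of an annotation track
#'
#' Splits annotated SNPs into k bins of (as near as possible) equal SNP
#' count by annotation value, ties broken by stable SNP order.  Missing
#' annotation values are excluded (bin NA).
#'
#' @param annotation an [annotation_track()].
#' @param k number of bins (default 5, quintiles).
#' @return list with `bin` (per-SNP integer label, NA where the annotation is
#'   missing), `edges` (k x 2 matrix of \[low, high) value edges), `k`.
#' @export
quantile_bins <- function(annotation, k = 5) {
  v <- annotation$value
  ok <- which(!is.na(v))
  if (length(unique(v[ok])) < k)
    stop_input("annotation '", annotation$name, "' has fewer than k = ", k,
               " distinct values; cannot form quantile bins")
  ord <- ok[order(v[ok])]                       # stable for ties
  m <- length(ord)
  sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
  bin <- rep(NA_integer_, length(v))
  bin[ord] <- rep(seq_len(k), times = sizes)
  edges <- t(vapply(seq_len(k), function(b) {
    range(v[which(bin == b)])
  }, numeric(2)))
  colnames(edges) <- c("low", "high")
  list(bin = bin, edges = edges, k = k, n_binned = m,
       n_missing = sum(is.na(v)))
}

# Re-window a subset of SNPs: consecutive runs of in-bin SNPs per chromosome.
rewindow_subset <- function(panel, idx, window_size) {
  sub <- subset_panel(panel, idx)
  sub$window_id <- NULL
  assign_windows(sub, window_size)
}

#' Per-annotation-bin variance decomposition
#'
#' Recomputes the covariance matrices and all statistics restricted to each
#' annotation quantile bin.  Windows are re-formed within each bin
#' (consecutive runs of in-bin SNPs, never spanning chromosomes) so the
#' block bootstrap keeps its local-LD blocking intent.  Per-interval
#' variances are reported raw and normalized by the bin's mean
#' heterozygosity at the interval's first time point.  A genome-wide
#' reference run uses `subsample_fraction = 1/k` so its CI width is
#' comparable to the bin CIs.
#'
#' @inheritParams decompose_variance
#' @param annotation an [annotation_track()] aligned with the panel.
#' @param k number of quantile bins (default 5).
#' @param window_size SNPs per re-formed window (default 1000).
#' @return An object of class `bin_decomposition`: `bins` (per-bin list with
#'   `result`, `edges`, `n_snps`, `interval_var` data.frame), `genomewide`
#'   (decomposition with 1/k-subsampled CIs), `binning` from
#'   [quantile_bins()].
#' @export
per_bin_decomposition <- function(panel, trajectory = NULL, sources = NULL,
                                  annotation, k = 5, window_size = 1000,
                                  boot = bootstrap_spec(),
                                  apply_D = TRUE, centered = FALSE) {
  check_aligned(panel, annotation, "annotation track")
  qb <- quantile_bins(annotation, k)
  bins <- vector("list", k)
  for (b in seq_len(k)) {
    idx <- which(qb$bin == b)
    sub <- rewindow_subset(panel, idx, window_size)
    sub_src <- if (is.null(sources)) NULL else
      source_panel(sources$snp_id[idx], sources$freq[idx, , drop = FALSE],
                   sources$n[idx, , drop = FALSE], sources$source_labels)
    nwin <- length(unique(sub$window_id))
    bboot <- boot
    if (nwin < 2 && !is.null(boot) && boot$n_boot > 0) {
      warning("bin ", b, " has < 2 windows: CI omitted, point estimate kept")
      bboot <- bootstrap_spec(0)
    }
    res <- decompose_variance(sub, trajectory, sub_src, apply_D = apply_D,
                              centered = centered, boot = bboot)
    cs <- res$covset
    ivar <- data.frame(interval = cs$interval_labels,
                       var_raw = diag(cs$R - cs$Ss),
                       het = cs$het0[seq_len(cs$K)],
                       stringsAsFactors = FALSE)
    ivar$var_norm <- ivar$var_raw / ivar$het
    bins[[b]] <- list(result = res, edges = qb$edges[b, ],
                      n_snps = length(idx), n_windows = nwin,
                      interval_var = ivar)
  }
  gw_boot <- if (is.null(boot)) NULL else
    bootstrap_spec(boot$n_boot, boot$conf, boot$seed,
                   subsample_fraction = 1 / k)
  gw_panel <- if (is.null(panel$window_id))
    assign_windows(panel, window_size) else panel
  genomewide <- decompose_variance(gw_panel, trajectory, sources,
                                   apply_D = apply_D, centered = centered,
                                   boot = gw_boot)
  structure(list(bins = bins, genomewide = genomewide, binning = qb, k = k,
                 annotation_name = annotation$name),
            class = "bin_decomposition")
}

#' Tidy per-bin statistics table
#'
#' @param x a `bin_decomposition`.
#' @return data.frame: bin, edge_low, edge_high, statistic, t, value,
#'   ci_low, ci_high.
#' @export
bin_stats_table <- function(x) {
  out <- lapply(seq_len(x$k), function(b) {
    df <- x$bins[[b]]$result$stats
    cbind(bin = b, edge_low = x$bins[[b]]$edges[1],
          edge_high = x$bins[[b]]$edges[2], df)
  })
  do.call(rbind, out)
}

#' @export
print.bin_decomposition <- function(x, ...) {
  cat(sprintf("bin_decomposition: %d bins of '%s' (%d SNPs binned, %d missing)\n",
              x$k, x$annotation_name, x$binning$n_binned, x$binning$n_missing))
  for (b in seq_len(x$k))
    cat(sprintf("  bin %d [%.4g, %.4g]: %d SNPs in %d windows\n", b,
                x$bins[[b]]$edges[1], x$bins[[b]]$edges[2],
                x$bins[[b]]$n_snps, x$bins[[b]]$n_windows))
  invisible(x)
}
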