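# Fixtures built in code; no data files.

# Panel whose per-interval changes are exactly `deltas` (L x K), starting
# from p0 = 0.5, with constant large n so noise corrections are negligible
# and no masking occurs.
panel_from_deltas <- function(deltas, n = 1e9, chrom = NULL,
                              window_size = NULL) {
  deltas <- as.matrix(deltas)
  L <- nrow(deltas)
  freq <- cbind(0.5, 0.5 + t(apply(deltas, 1L, cumsum)))
  stopifnot(all(freq >= 0 & freq <= 1))
  if (is.null(chrom)) chrom <- rep("1", L)
  p <- freq_panel(paste0("s", seq_len(L)), chrom, seq_len(L), freq,
                  matrix(n, L, ncol(freq)))
  if (!is.null(window_size)) p <- assign_windows(p, window_size)
  p
}

# Small deterministic pseudohaploid sampled panel: fixed true frequencies,
# binomial pseudohaploid resampling at each time point.
sampled_panel <- function(L = 1000, Tn = 3, n = 30, p = NULL,
                          window_size = NULL) {
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  freq <- sapply(seq_len(Tn), function(i) rbinom(L, n, p) / n)
  pan <- freq_panel(paste0("s", seq_len(L)), rep("1", L), seq_len(L),
                    freq, matrix(n, L, Tn))
  if (!is.null(window_size)) pan <- assign_windows(pan, window_size)
  pan
}

# Brute-force double-loop oracle for the across-SNP moment matrix.
naive_moment_matrix <- function(d, centered = FALSE) {
  K <- ncol(d)
  if (centered) for (j in seq_len(K)) d[, j] <- d[, j] - mean(d[, j])
  M <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- 0
    for (l in seq_len(nrow(d))) s <- s + d[l, i] * d[l, j]
    M[i, j] <- s / nrow(d)
  }
  M
}

# Flip the reference allele at a subset of SNPs in panel (+ sources).
flip_polarity <- function(panel, sources = NULL, idx) {
  panel$freq[idx, ] <- 1 - panel$freq[idx, ]
  out <- list(panel = panel)
  if (!is.null(sources)) {
    sources$freq[idx, ] <- 1 - sources$freq[idx, ]
    out$sources <- sources
  }
  out
}

# Two-source trajectory from explicit pulse proportions (m = 0 means no
# pulse in that interval); pulses always from source 2.
traj_from_pulses <- function(m_by_interval, labels = NULL) {
  Tn <- length(m_by_interval) + 1L
  alpha <- matrix(NA_real_, Tn, 2)
  alpha[1, ] <- c(1, 0)
  for (i in seq_along(m_by_interval)) {
    m <- m_by_interval[i]
    alpha[i + 1L, ] <- (1 - m) * alpha[i, ] + m * c(0, 1)
  }
  ancestry_traj(alpha, time_labels = labels)
}
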