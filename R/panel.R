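#' @keywords internal
"_PACKAGE"

# Internal condition helpers: input/schema problems get class
# "tempocov_input_error" (CLI exit code 2), numerical failures get
# "tempocov_numeric_error" (exit code 3).
stop_input <- function(...) {
  stop(structure(class = c("tempocov_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_numeric <- function(...) {
  stop(structure(class = c("tempocov_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Temporal allele-frequency panel
#'
#' Container for a SNP x time-point table of sample allele frequencies from a
#' single focal population, as produced from pooled (pseudohaploid) genotype
#' calls at a set of discrete time points.  Frequencies refer to a fixed but
#' arbitrary allele per SNP; every statistic downstream is invariant to
#' flipping that choice.
#'
#' @param snp_id character vector of SNP identifiers (length L).
#' @param chrom chromosome per SNP (character or integer, length L).
#' @param pos 1-based base-pair position per SNP (length L).
#' @param freq L x T numeric matrix of sample allele frequencies; entries at
#'   time points where the SNP is unobserved must be `NA`.
#' @param n L x T numeric matrix of haploid (pseudohaploid) sample sizes;
#'   `0` marks a missing observation.
#' @param time_labels length-T character labels of the time points, ordered
#'   oldest to youngest.
#' @param ages numeric ages of the time points (years BP or generations BP),
#'   strictly decreasing (oldest first).
#' @param window_id optional per-SNP window index (see [assign_windows()]).
#'
#' @return An object of class `freq_panel`: a list with fields `snp_id`,
#'   `chrom`, `pos`, `freq`, `n`, `time_labels`, `ages`, `window_id`.
#' @seealso [frequencies_from_genotypes()], [read_panel()], [assign_windows()]
#' @export
freq_panel <- function(snp_id, chrom, pos, freq, n, time_labels = NULL,
                       ages = NULL, window_id = NULL) {
  freq <- as.matrix(freq); n <- as.matrix(n)
  L <- length(snp_id)
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(ncol(freq)) - 1L)
  if (is.null(ages)) ages <- rev(seq_len(ncol(freq))) - 1
  if (nrow(freq) != L || nrow(n) != L || length(chrom) != L || length(pos) != L)
    stop_input("panel fields disagree on the number of SNPs")
  if (!identical(dim(freq), dim(n)))
    stop_input("freq and n matrices must have identical dimensions")
  if (ncol(freq) != length(time_labels) || length(ages) != length(time_labels))
    stop_input("number of time points inconsistent between freq, labels and ages")
  if (length(ages) > 1 && any(diff(ages) >= 0))
    stop_input("ages must be strictly decreasing (oldest time point first)")
  freq[n == 0] <- NA_real_
  obs <- n > 0
  if (any(obs & (is.na(freq) | freq < 0 | freq > 1)))
    stop_input("frequencies must lie in [0,1] wherever n > 0")
  if (any(n < 0)) stop_input("sample sizes must be >= 0")
  dimnames(freq) <- dimnames(n) <- list(NULL, time_labels)
  structure(list(snp_id = as.character(snp_id), chrom = as.character(chrom),
                 pos = as.integer(pos), freq = freq, n = n,
                 time_labels = time_labels, ages = as.numeric(ages),
                 window_id = window_id),
            class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat(sprintf("freq_panel: %d SNPs x %d time points\n", nrow(x$freq), ncol(x$freq)))
  cat("  time points:", paste(sprintf("%s (%g)", x$time_labels, x$ages),
                              collapse = ", "), "\n")
  if (!is.null(x$window_id))
    cat(sprintf("  windows: %d\n", length(unique(x$window_id))))
  invisible(x)
}

#' Number of time points / intervals of a panel
#' @param panel a [freq_panel()].
#' @return integer.
#' @export
n_timepoints <- function(panel) ncol(panel$freq)

#' @rdname n_timepoints
#' @export
n_intervals <- function(panel) ncol(panel$freq) - 1L

#' Source-proxy allele-frequency panel
#'
#' Sample allele frequencies of the proxy samples used to represent the
#' sources of admixture, aligned SNP-for-SNP with the focal
#' [freq_panel()].
#'
#' @param snp_id character vector of SNP identifiers, in the same order as the
#'   focal panel.
#' @param freq L x R matrix of sample frequencies in each source proxy.
#' @param n L x R matrix of haploid sample sizes (0 = missing).
#' @param source_labels length-R character names of the sources.
#' @return An object of class `source_panel`.
#' @export
source_panel <- function(snp_id, freq, n, source_labels = NULL) {
  freq <- as.matrix(freq); n <- as.matrix(n)
  if (is.null(source_labels)) source_labels <- paste0("src", seq_len(ncol(freq)))
  if (nrow(freq) != length(snp_id) || !identical(dim(freq), dim(n)))
    stop_input("source panel fields disagree on dimensions")
  freq[n == 0] <- NA_real_
  if (any(n > 0 & (is.na(freq) | freq < 0 | freq > 1)))
    stop_input("source frequencies must lie in [0,1] wherever n > 0")
  dimnames(freq) <- dimnames(n) <- list(NULL, source_labels)
  structure(list(snp_id = as.character(snp_id), freq = freq, n = n,
                 source_labels = source_labels),
            class = "source_panel")
}

#' @export
print.source_panel <- function(x, ...) {
  cat(sprintf("source_panel: %d SNPs x %d sources (%s)\n", nrow(x$freq),
              ncol(x$freq), paste(x$source_labels, collapse = ", ")))
  invisible(x)
}

#' Ancestry trajectory
#'
#' Mean ancestry proportions of the focal population from R admixture sources
#' at each panel time point, e.g. qpAdm point estimates.  Consumed as given;
#' this package does not infer ancestry proportions.
#'
#' @param alpha T x R matrix; each row must sum to 1 (tolerance `tol`).
#' @param time_labels,ages as in [freq_panel()]; must match the focal panel.
#' @param source_labels length-R source names; must match the
#'   [source_panel()].
#' @param tol tolerance on the row-sum invariant.
#' @return An object of class `ancestry_traj` with fields `alpha` (T x R) and
#'   `delta_alpha` ((T-1) x R), where
#'   `delta_alpha[t, r] = alpha[t+1, r] - alpha[t, r]`.
#' @export
ancestry_traj <- function(alpha, time_labels = NULL, ages = NULL,
                          source_labels = NULL, tol = 1e-6) {
  alpha <- as.matrix(alpha)
  if (is.null(source_labels)) source_labels <- colnames(alpha)
  if (is.null(source_labels)) source_labels <- paste0("src", seq_len(ncol(alpha)))
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(nrow(alpha)) - 1L)
  if (any(alpha < -tol) || any(alpha > 1 + tol))
    stop_input("ancestry proportions must lie in [0,1]")
  bad <- which(abs(rowSums(alpha) - 1) > tol)
  if (length(bad))
    stop_input("ancestry rows must sum to 1; offending row(s): ",
               paste(bad, collapse = ", "))
  dimnames(alpha) <- list(time_labels, source_labels)
  da <- alpha[-1L, , drop = FALSE] - alpha[-nrow(alpha), , drop = FALSE]
  structure(list(alpha = alpha, delta_alpha = da, time_labels = time_labels,
                 ages = ages, source_labels = source_labels),
            class = "ancestry_traj")
}

#' @export
print.ancestry_traj <- function(x, ...) {
  cat(sprintf("ancestry_traj: %d time points x %d sources\n",
              nrow(x$alpha), ncol(x$alpha)))
  print(round(x$alpha, 4))
  invisible(x)
}

#' Per-SNP annotation track
#'
#' A scalar genomic annotation (e.g. local recombination rate in cM/Mb, or
#' B-value in \[0,1\]) aligned to the panel's SNP order.  Missing values stay
#' `NA`; they are excluded from quantile binning, never zero-filled.
#'
#' @param snp_id SNP identifiers aligned to the panel.
#' @param value numeric vector of annotation values (NA = missing).
#' @param name annotation name.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(snp_id, value, name = "annotation") {
  if (length(snp_id) != length(value))
    stop_input("annotation value vector must align with snp_id")
  structure(list(snp_id = as.character(snp_id), value = as.numeric(value),
                 name = name),
            class = "annotation_track")
}

# Check SNP alignment between focal panel and companion objects.
check_aligned <- function(panel, x, what = "source panel") {
  if (nrow(panel$freq) != length(x$snp_id) ||
      !identical(panel$snp_id, x$snp_id)) {
    off <- which(panel$snp_id[seq_len(min(length(panel$snp_id),
                                          length(x$snp_id)))] !=
                 x$snp_id[seq_len(min(length(panel$snp_id), length(x$snp_id)))])
    stop_input(what, " is not SNP-aligned with the panel",
               if (length(off)) paste0(" (first mismatch at row ", off[1], ")"))
  }
  invisible(TRUE)
}
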