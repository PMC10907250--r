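#' Pooled sample frequencies from pseudohaploid genotype calls
#'
#' Pools individuals by time-point label and computes, per SNP and time point,
#' the sample allele frequency and the haploid sample size (count of
#' non-missing calls).  Only pseudohaploid calls (one randomly drawn allele
#' per individual, coded 0/1, missing allowed) are accepted: the downstream
#' sampling-noise corrections assume one haploid draw per individual, and
#' diploid 0/1/2 matrices are rejected rather than silently halving.
#'
#' @param genotypes L x N matrix of pseudohaploid calls: 0, 1, or
#'   `missing_code`.
#' @param group_assignment length-N vector assigning each individual (column)
#'   to a time-point label.
#' @param group_order optional vector giving the time-point labels oldest to
#'   youngest; defaults to order of first appearance.
#' @param ages optional numeric ages per time point (oldest first).
#' @param snp_id,chrom,pos per-SNP metadata; defaults are generated.
#' @param missing_code value marking a missing call (default 9, as in
#'   EIGENSTRAT-style data).
#' @return A [freq_panel()] with `n[i, l]` = non-missing calls and
#'   `freq[i, l]` = allele-1 count / n.
#' @export
frequencies_from_genotypes <- function(genotypes, group_assignment,
                                       group_order = NULL, ages = NULL,
                                       snp_id = NULL, chrom = NULL, pos = NULL,
                                       missing_code = 9) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(group_assignment))
    stop_input("group_assignment must have one entry per genotype column")
  vals <- unique(as.vector(genotypes))
  vals <- vals[!is.na(vals)]
  if (any(!vals %in% c(0, 1, missing_code)))
    stop_input("pseudohaploid calls required: genotype values must be 0, 1 or ",
               missing_code, " (got ",
               paste(utils::head(setdiff(vals, c(0, 1, missing_code)), 3),
                     collapse = ", "), ")")
  group_assignment <- as.character(group_assignment)
  if (is.null(group_order)) group_order <- unique(group_assignment)
  if (!all(group_assignment %in% group_order))
    stop_input("group_assignment contains labels absent from group_order")
  if (!all(group_order %in% group_assignment))
    stop_input("empty time-point group(s): ",
               paste(setdiff(group_order, group_assignment), collapse = ", "))
  L <- nrow(genotypes)
  miss <- genotypes == missing_code | is.na(genotypes)
  ones <- genotypes == 1 & !miss
  n <- sapply(group_order, function(g) {
    idx <- group_assignment == g
    rowSums(!miss[, idx, drop = FALSE])
  })
  cnt <- sapply(group_order, function(g) {
    idx <- group_assignment == g
    rowSums(ones[, idx, drop = FALSE])
  })
  n <- matrix(n, nrow = L); cnt <- matrix(cnt, nrow = L)
  freq <- ifelse(n > 0, cnt / pmax(n, 1), NA_real_)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(L))
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L)
  freq_panel(snp_id, chrom, pos, freq, n, time_labels = group_order,
             ages = ages)
}

#' Read an EIGENSTRAT plain-text genotype triple
#'
#' Reads `.geno` (one row per SNP, one digit per individual, 9 = missing),
#' `.snp` (snp id, chromosome, genetic position, physical position, alleles)
#' and `.ind` (individual id, sex, group label) files and pools individuals
#' by their `.ind` group label into a [freq_panel()].  Calls must be
#' pseudohaploid (0/1/9); the packed binary PACKEDANCESTRYMAP variant is not
#' supported.
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   must exist.
#' @param group_order,ages passed to [frequencies_from_genotypes()].
#' @return A [freq_panel()].
#' @export
read_eigenstrat <- function(prefix, group_order = NULL, ages = NULL) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop_input("missing file: ", p)
  geno_lines <- readLines(paths[1])
  snp <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE)
  ind <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE)
  if (length(geno_lines) != nrow(snp))
    stop_input(".geno has ", length(geno_lines), " rows but .snp has ",
               nrow(snp))
  nind <- nrow(ind)
  if (any(nchar(geno_lines) != nind))
    stop_input(".geno row width does not match the number of individuals (",
               nind, "); first offending row: ",
               which(nchar(geno_lines) != nind)[1])
  g <- matrix(as.integer(unlist(strsplit(geno_lines, "", fixed = TRUE))),
              nrow = length(geno_lines), byrow = TRUE)
  frequencies_from_genotypes(g, ind[[3]], group_order = group_order,
                             ages = ages, snp_id = snp[[1]],
                             chrom = as.character(snp[[2]]), pos = snp[[4]])
}

#' Filter loci on minimum sample sizes
#'
#' Keeps a SNP only if its haploid sample size is strictly greater than
#' `min_n_timepoint` at every time point and strictly greater than
#' `min_n_source` in every source proxy (when `sources` is given).  Strict
#' inequality mirrors the usual "more than k genotypes" phrasing of aDNA
#' panel filters.
#'
#' @param panel a [freq_panel()].
#' @param sources optional aligned [source_panel()].
#' @param min_n_timepoint,min_n_source integer thresholds (strict `>`).
#' @param quiet suppress the kept/dropped message.
#' @return A list with the filtered `panel`, filtered `sources` (or NULL),
#'   logical `keep`, and counts `n_kept`, `n_dropped`.
#' @export
filter_loci <- function(panel, sources = NULL, min_n_timepoint = 10,
                        min_n_source = 5, quiet = FALSE) {
  keep <- apply(panel$n > min_n_timepoint, 1L, all)
  if (!is.null(sources)) {
    check_aligned(panel, sources)
    keep <- keep & apply(sources$n > min_n_source, 1L, all)
  }
  if (!any(keep)) warning("no SNPs pass the sample-size filters")
  out_panel <- subset_panel(panel, keep)
  out_sources <- if (is.null(sources)) NULL else
    source_panel(sources$snp_id[keep],
                 sources$freq[keep, , drop = FALSE],
                 sources$n[keep, , drop = FALSE], sources$source_labels)
  if (!quiet)
    message(sprintf("filter_loci: kept %d / %d SNPs (dropped %d)",
                    sum(keep), length(keep), sum(!keep)))
  list(panel = out_panel, sources = out_sources, keep = keep,
       n_kept = sum(keep), n_dropped = sum(!keep))
}

# Row-subset a freq_panel.
subset_panel <- function(panel, idx) {
  freq_panel(panel$snp_id[idx], panel$chrom[idx], panel$pos[idx],
             panel$freq[idx, , drop = FALSE], panel$n[idx, , drop = FALSE],
             time_labels = panel$time_labels, ages = panel$ages,
             window_id = panel$window_id[idx])
}

#' Assign SNPs to genomic windows by SNP count
#'
#' Forms windows of `window_size` consecutive SNPs within each chromosome for
#' block-bootstrap resampling.  The terminal window on each chromosome may be
#' smaller; windows never span chromosomes.  Windowing is by SNP count, not
#' physical length, so every full window carries equal information for the
#' bootstrap.
#'
#' @param panel a [freq_panel()] with SNPs sorted by (chromosome, position).
#' @param window_size SNPs per window (default 1000).
#' @return The panel with `window_id` set (integer, 1-based, consecutive).
#' @export
assign_windows <- function(panel, window_size = 1000) {
  if (window_size < 1) stop_input("window_size must be >= 1")
  chrom <- panel$chrom
  for (ch in unique(chrom)) {
    p <- panel$pos[chrom == ch]
    if (is.unsorted(p))
      stop_input("SNPs must be sorted by position within chromosome ", ch)
  }
  runs <- rle(chrom)
  if (any(duplicated(runs$values)))
    stop_input("SNPs must be grouped by chromosome")
  wid <- integer(length(chrom))
  next_id <- 1L
  offset <- 0L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    local <- (seq_len(len) - 1L) %/% window_size
    wid[offset + seq_len(len)] <- next_id + local
    next_id <- next_id + max(local) + 1L
    offset <- offset + len
  }
  panel$window_id <- wid
  panel
}
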