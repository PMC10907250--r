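# Native TSV schemas
#
# panel:      snp, chrom, pos, [window], freq_<label>, n_<label> per time
#             point; a "#ages:" comment line carries the numeric ages.
# sources:    snp, freq_<label>, n_<label> per source.
# trajectory: time, age, alpha_<label> per source.
# annotation: snp, value.

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_input("file ", path, " lacks required column(s): ",
               paste(miss, collapse = ", "))
}

#' Read / write a temporal frequency panel as TSV
#'
#' Native tab-separated format: columns `snp`, `chrom`, `pos`, optional
#' `window`, then `freq_<label>` and `n_<label>` for each time point, with a
#' leading `#ages:` comment line holding the time-point ages.  Write-then-read
#' is the identity.
#'
#' @param panel a [freq_panel()].
#' @param path file path.
#' @return `read_panel` returns a [freq_panel()]; `write_panel` returns the
#'   path invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(snp = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
                   stringsAsFactors = FALSE)
  if (!is.null(panel$window_id)) df$window <- panel$window_id
  for (j in seq_along(panel$time_labels)) {
    df[[paste0("freq_", panel$time_labels[j])]] <- panel$freq[, j]
    df[[paste0("n_", panel$time_labels[j])]] <- panel$n[, j]
  }
  write_tsv(df, path,
            paste0("#ages: ", paste(panel$ages, collapse = "\t")))
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  first <- readLines(path, n = 1L)
  ages <- NULL
  if (startsWith(first, "#ages:"))
    ages <- as.numeric(strsplit(sub("^#ages:\\s*", "", first), "\t")[[1]])
  df <- read_tsv(path)
  require_cols(df, c("snp", "chrom", "pos"), path)
  fcols <- grep("^freq_", names(df), value = TRUE)
  labels <- sub("^freq_", "", fcols)
  ncols <- paste0("n_", labels)
  require_cols(df, ncols, path)
  freq <- as.matrix(df[fcols]); n <- as.matrix(df[ncols])
  bad <- which(n > 0 & (is.na(freq) | freq < 0 | freq > 1))
  if (length(bad))
    stop_input("panel ", path, ": frequency outside [0,1] at data row ",
               ((bad[1] - 1) %% nrow(freq)) + 1)
  freq_panel(df$snp, df$chrom, df$pos, freq, n, time_labels = labels,
             ages = ages, window_id = df$window)
}

#' Read / write a source-proxy panel as TSV
#'
#' Columns `snp`, then `freq_<label>`, `n_<label>` per source.
#' @param sources a [source_panel()].
#' @param path file path.
#' @return `read_sources` returns a [source_panel()].
#' @export
write_sources <- function(sources, path) {
  df <- data.frame(snp = sources$snp_id, stringsAsFactors = FALSE)
  for (j in seq_along(sources$source_labels)) {
    df[[paste0("freq_", sources$source_labels[j])]] <- sources$freq[, j]
    df[[paste0("n_", sources$source_labels[j])]] <- sources$n[, j]
  }
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_sources
#' @export
read_sources <- function(path) {
  df <- read_tsv(path)
  require_cols(df, "snp", path)
  fcols <- grep("^freq_", names(df), value = TRUE)
  labels <- sub("^freq_", "", fcols)
  require_cols(df, paste0("n_", labels), path)
  source_panel(df$snp, as.matrix(df[fcols]),
               as.matrix(df[paste0("n_", labels)]), labels)
}

#' Read / write an ancestry trajectory as TSV
#'
#' Columns `time`, `age`, then `alpha_<label>` per source.  Rows whose
#' ancestry proportions do not sum to 1 within `tol` are rejected with their
#' row number.
#'
#' @param traj an [ancestry_traj()].
#' @param path file path.
#' @param tol row-sum tolerance.
#' @return `read_trajectory` returns an [ancestry_traj()].
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$time_labels,
                   age = if (is.null(traj$ages)) NA_real_ else traj$ages,
                   stringsAsFactors = FALSE)
  for (j in seq_along(traj$source_labels))
    df[[paste0("alpha_", traj$source_labels[j])]] <- traj$alpha[, j]
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, tol = 1e-6) {
  df <- read_tsv(path)
  require_cols(df, c("time", "age"), path)
  acols <- grep("^alpha_", names(df), value = TRUE)
  if (!length(acols)) stop_input("file ", path, " has no alpha_<source> columns")
  alpha <- as.matrix(df[acols])
  bad <- which(abs(rowSums(alpha) - 1) > tol)
  if (length(bad))
    stop_input("trajectory ", path, ": ancestry row(s) not summing to 1: row ",
               paste(bad, collapse = ", "))
  ages <- df$age
  if (all(is.na(ages))) ages <- NULL
  ancestry_traj(alpha, time_labels = as.character(df$time), ages = ages,
                source_labels = sub("^alpha_", "", acols), tol = tol)
}

#' Read / write an annotation track as TSV
#'
#' Columns `snp`, `value`.  Missing values may be written as NA; they stay
#' missing (excluded from binning, never zero-filled).
#'
#' @param annotation an [annotation_track()].
#' @param path file path.
#' @param name annotation name for the returned object.
#' @return `read_annotation` returns an [annotation_track()].
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(data.frame(snp = annotation$snp_id, value = annotation$value,
                       stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, name = NULL) {
  df <- read_tsv(path)
  require_cols(df, c("snp", "value"), path)
  annotation_track(df$snp, df$value,
                   name = if (is.null(name))
                     sub("\\.tsv$", "", basename(path)) else name)
}

#' Serialize a covariance set as a TSV bundle
#'
#' Writes one `<name>.tsv` per component matrix (K x K with interval labels)
#' plus a `covset_meta.json` sidecar recording the masking and centering
#' rules and per-window SNP counts.
#'
#' @param covset a `covariance_set` from [corrected_cov_matrix()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_covset <- function(covset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("R", "Ss", "A_adm", "SA", "D", "C")) {
    m <- covset[[nm]]
    df <- as.data.frame(m)
    names(df) <- covset$interval_labels
    df <- cbind(interval = covset$interval_labels, df)
    write_tsv(df, file.path(dir, paste0(nm, ".tsv")))
  }
  meta <- list(centered = covset$centered, sa_sign = covset$sa_sign,
               masking = "pairwise: SNP contributes to entry (i,j) iff observed at all time points bounding intervals i and j",
               window_weights = covset$weights,
               n_snps = covset$n_snps)
  jsonlite::write_json(meta, file.path(dir, "covset_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialize a decomposition result as tidy TSV
#'
#' One row per (statistic, t): columns `statistic`, `t`, `value`, `ci_low`,
#' `ci_high` — suitable for plotting A/G/Gnc curves over time.
#'
#' @param result a `decomposition_result` from [decompose_variance()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_decomposition <- function(result, path) {
  write_tsv(result$stats, path)
  invisible(path)
}
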