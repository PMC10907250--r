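test_that("frequencies_from_genotypes counts pseudohaploid calls correctly", {
  g <- rbind(c(1, 1, 0, 9),
             c(9, 9, 9, 9),
             c(0, 0, 1, 1))
  pan <- frequencies_from_genotypes(g, rep("t0", 4))
  expect_equal(unname(pan$freq[1, 1]), 2 / 3)
  expect_equal(unname(pan$n[1, 1]), 3)
  expect_equal(unname(pan$n[2, 1]), 0)  # all-missing SNP
  expect_true(is.na(pan$freq[2, 1]))
  expect_equal(unname(pan$freq[3, 1]), 0.5)

  # conservation: n summed over groups equals total non-missing calls
  g2 <- matrix(sample(c(0, 1, 9), 200, TRUE), 10, 20)
  grp <- rep(c("a", "b"), each = 10)
  pan2 <- frequencies_from_genotypes(g2, grp)
  expect_equal(rowSums(pan2$n), rowSums(g2 != 9))
})

test_that("diploid and malformed genotype input is rejected", {
  g <- rbind(c(0, 1, 2))
  expect_error(frequencies_from_genotypes(g, c("a", "a", "a")),
               "pseudohaploid")
  expect_error(frequencies_from_genotypes(rbind(c(0, 1)), c("a", "b"),
                                          group_order = c("a", "b", "c")),
               "empty")
})

test_that("filter_loci applies strict thresholds and is idempotent", {
  n <- rbind(c(11, 11), c(10, 11), c(12, 30))   # threshold 10: row 2 out
  freq <- matrix(0.5, 3, 2)
  pan <- freq_panel(paste0("s", 1:3), rep("1", 3), 1:3, freq, n)
  src <- source_panel(pan$snp_id, matrix(0.4, 3, 1),
                      matrix(c(6, 6, 5), 3, 1))   # threshold 5: row 3 out
  fl <- suppressMessages(filter_loci(pan, src, 10, 5))
  expect_equal(fl$keep, c(TRUE, FALSE, FALSE))
  expect_equal(fl$n_kept, 1)
  # brute-force per-row scan agrees
  brute <- sapply(1:3, function(l) all(n[l, ] > 10) && all(src$n[l, ] > 5))
  expect_equal(fl$keep, brute)
  # idempotent
  fl2 <- suppressMessages(filter_loci(fl$panel, fl$sources, 10, 5))
  expect_equal(fl2$n_dropped, 0)
  expect_equal(fl2$panel$freq, fl$panel$freq)
  # zero thresholds keep fully observed SNPs
  fl0 <- suppressMessages(filter_loci(pan, src, 0, 0))
  expect_equal(fl0$n_kept, 3)
})

test_that("assign_windows forms per-chromosome SNP-count windows", {
  mk <- function(L, chrom) {
    pos <- ave(seq_len(L), chrom, FUN = seq_along)
    freq_panel(paste0("s", 1:L), chrom, pos, matrix(0.5, L, 2),
               matrix(10, L, 2))
  }
  p1 <- assign_windows(mk(2500, rep("1", 2500)), 1000)
  expect_equal(as.vector(table(p1$window_id)), c(1000, 1000, 500))
  p2 <- assign_windows(mk(999, rep("1", 999)), 1000)
  expect_equal(unique(p2$window_id), 1L)
  p3 <- assign_windows(mk(3000, rep(c("1", "2"), each = 1500)), 1000)
  expect_equal(as.vector(table(p3$window_id)), c(1000, 500, 1000, 500))
  # windows partition SNPs and never span chromosomes
  expect_equal(length(unique(paste(p3$chrom, p3$window_id))),
               length(unique(p3$window_id)))
  # unsorted input rejected
  bad <- mk(10, rep("1", 10)); bad$pos <- rev(bad$pos)
  expect_error(assign_windows(bad, 5), "sorted")
})

test_that("panel/sources/trajectory/annotation TSV round-trips are identity", {
  set.seed(3)
  pan <- assign_windows(sampled_panel(50, 3), 20)
  tmp <- tempfile(fileext = ".tsv")
  write_panel(pan, tmp)
  pan2 <- read_panel(tmp)
  expect_equal(pan2$freq, pan$freq)
  expect_equal(pan2$n, pan$n)
  expect_equal(pan2$ages, pan$ages)
  expect_equal(pan2$window_id, pan$window_id)

  src <- source_panel(pan$snp_id, matrix(runif(100), 50, 2),
                      matrix(30, 50, 2), c("a", "b"))
  ts <- tempfile(fileext = ".tsv"); write_sources(src, ts)
  src2 <- read_sources(ts)
  expect_equal(src2$freq, src$freq)
  expect_equal(src2$source_labels, src$source_labels)

  traj <- traj_from_pulses(c(0.1, 0, 0.2))
  tt <- tempfile(fileext = ".tsv"); write_trajectory(traj, tt)
  traj2 <- read_trajectory(tt)
  expect_equal(traj2$alpha, traj$alpha)
  expect_equal(traj2$delta_alpha, traj$delta_alpha)

  ann <- annotation_track(pan$snp_id, c(runif(49), NA), "bval")
  ta <- tempfile(fileext = ".tsv"); write_annotation(ann, ta)
  ann2 <- read_annotation(ta)
  expect_equal(ann2$value, ann$value)
})

test_that("schema violations are rejected with context", {
  tt <- tempfile(fileext = ".tsv")
  writeLines(c("time\tage\talpha_a\talpha_b", "t0\t100\t0.5\t0.3"), tt)
  expect_error(read_trajectory(tt), "row.*1")
  expect_error(ancestry_traj(rbind(c(0.5, 0.3))), "sum to 1")
  tp <- tempfile(fileext = ".tsv")
  writeLines(c("snp\tchrom\tpos\tfreq_t0\tn_t0", "s1\t1\t1\t1.5\t10"), tp)
  expect_error(read_panel(tp), "\\[0,1\\]")
})

test_that("EIGENSTRAT plain-text triple is read with 9 as missing", {
  pre <- tempfile()
  writeLines(c("019", "110", "909"), paste0(pre, ".geno"))
  writeLines(c("rs1 1 0.0 100 A G", "rs2 1 0.0 200 A G", "rs3 1 0.0 300 A G"),
             paste0(pre, ".snp"))
  writeLines(c("i1 M old", "i2 F old", "i3 M new"), paste0(pre, ".ind"))
  pan <- read_eigenstrat(pre)
  expect_equal(pan$time_labels, c("old", "new"))
  expect_equal(unname(pan$n[, 1]), c(2, 2, 1))   # 9s are missing
  expect_equal(unname(pan$freq[1, 1]), 0.5)
  expect_equal(unname(pan$freq[2, 2]), 0)
  expect_equal(pan$pos, c(100L, 200L, 300L))
  # malformed width
  writeLines(c("01", "110", "909"), paste0(pre, ".geno"))
  expect_error(read_eigenstrat(pre), "width")
})
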