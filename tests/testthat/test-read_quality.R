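as_reads <- function(seqs, quals) {
  list(sequences = Biostrings::DNAStringSet(setNames(seqs, sprintf("r%d", seq_along(seqs)))),
       qualities = quals)
}

test_that("per-read GC and median Phred follow their definitions", {
  reads <- as_reads(c("GGCC", "ACGT"), list(rep(30L, 4), c(10L, 20L, 30L, 40L)))
  rq <- read_gc_quality(reads)
  expect_equal(rq$gc_percent, c(100, 50))
  expect_equal(rq$median_phred, c(30, 25))    # even length: mean of central pair
  expect_identical(rq$gc_bin, c(100L, 50L))

  # GC over unambiguous bases only; all-N reads skipped with a message
  mixed <- as_reads(c("GCNN", "NNNN"), list(rep(20L, 4), rep(20L, 4)))
  expect_message(rq2 <- read_gc_quality(mixed), "skipped")
  expect_identical(nrow(rq2), 1L)
  expect_equal(rq2$gc_percent, 100)

  expect_error(read_gc_quality(as_reads(character(), list())), "no reads")
})

test_that("per-bin boxplot statistics match brute-force percentiles", {
  asm <- gradient_assembly(seed = 61, seg_len = 3000L, gcs = c(30, 50, 70))
  qm <- quality_model(base_phred = 35, degrade_above_gc = 55,
                      degrade_slope = 1, noise_sd = 3)
  reads <- simulate_fastq(asm, bias_none(), qm, n_reads = 1000, seed = 62)
  rq <- read_gc_quality(reads)
  stats <- quality_bin_stats(rq)
  expect_true(all(stats$q1 <= stats$median & stats$median <= stats$q3))
  expect_true(all(stats$p10 <= stats$q1 & stats$q3 <= stats$p90))
  for (b in sample(stats$gc_bin, 10)) {
    v <- rq$median_phred[rq$gc_bin == b]
    row <- stats[stats$gc_bin == b, ]
    expect_equal(unlist(row[c("median", "q1", "q3", "p10", "p90")], use.names = FALSE),
                 unname(quantile(v, c(0.5, 0.25, 0.75, 0.1, 0.9), type = 7)),
                 tolerance = 1e-12)
  }
  expect_identical(sum(stats$n_reads), nrow(rq))
})

test_that("proportion ratios compare identical-bin GC histograms", {
  asm <- gradient_assembly(seed = 63, seg_len = 2000L, gcs = c(35, 55, 75))
  qm <- quality_model()
  reads <- simulate_fastq(asm, bias_none(), qm, n_reads = 800, seed = 64)
  rq <- read_gc_quality(reads)

  same <- filter_proportion_ratios(rq, rq)
  expect_true(all(same$ratio == 1))
  expect_equal(sum(same$proportion_filtered), 1, tolerance = 1e-12)
  expect_equal(sum(same$proportion_unfiltered), 1, tolerance = 1e-12)

  # filtering away everything above 65% GC forces ratio 0 in those bins
  kept <- rq[rq$gc_percent <= 65, ]
  res <- filter_proportion_ratios(kept, rq)
  high <- res$gc_bin > 65
  expect_true(any(high))
  expect_true(all(res$ratio[high] == 0))
  expect_true(all(res$n_filtered[high] == 0))
  # renormalization pushes surviving bins slightly above 1
  expect_true(all(res$ratio[!high] >= 1))

  expect_identical(res$abundant, res$proportion_unfiltered >= 0.001)
  expect_error(filter_proportion_ratios(rq, rq, bin_width = 0), "positive")
})

test_that("median-Phred filtering interacts with GC-dependent quality decay", {
  asm <- gradient_assembly(seed = 65, seg_len = 12000L,
                           gcs = seq(30, 78, by = 4))
  qm <- quality_model(base_phred = 37, degrade_above_gc = 65,
                      degrade_slope = 4, noise_sd = 1.5)
  reads <- simulate_fastq(asm, bias_none(), qm, n_reads = 12000, seed = 66)
  filt <- filter_reads_by_median_quality(reads, min_median = 30)
  expect_lt(length(filt$sequences), length(reads$sequences))

  res <- filter_proportion_ratios(read_gc_quality(filt), read_gc_quality(reads))
  # brute-force recheck of the histogram division for a handful of bins
  rq_u <- read_gc_quality(reads); rq_f <- read_gc_quality(filt)
  for (b in c(40, 60, 70)) {
    expect_equal(res$ratio[res$gc_bin == b],
                 (sum(rq_f$gc_bin == b) / nrow(rq_f)) /
                   (sum(rq_u$gc_bin == b) / nrow(rq_u)),
                 tolerance = 1e-12)
  }
  # reads well below the degradation threshold are essentially untouched;
  # reads above it are depleted
  low <- res$abundant & res$gc_bin <= 60
  high <- res$abundant & res$gc_bin > 68
  expect_true(all(res$ratio[low] > 0.95))
  expect_true(all(res$ratio[high] < 1))
})

test_that("ratios are stable under joint subsampling", {
  asm <- gradient_assembly(seed = 67, seg_len = 6000L, gcs = seq(35, 65, by = 10))
  qm <- quality_model(base_phred = 37, degrade_above_gc = 55,
                      degrade_slope = 2, noise_sd = 3)
  reads <- simulate_fastq(asm, bias_none(), qm, n_reads = 8000, seed = 68)
  filt <- filter_reads_by_median_quality(reads, min_median = 33)
  rq_u <- read_gc_quality(reads); rq_f <- read_gc_quality(filt)
  full <- filter_proportion_ratios(rq_f, rq_u)

  set.seed(69)
  sub_u <- rq_u[runif(nrow(rq_u)) < 0.5, ]
  sub_f <- rq_f[runif(nrow(rq_f)) < 0.5, ]
  half <- filter_proportion_ratios(sub_f, sub_u)
  common <- intersect(full$gc_bin[full$abundant & full$n_filtered >= 50],
                      half$gc_bin)
  expect_gt(length(common), 3)
  i_f <- match(common, full$gc_bin); i_h <- match(common, half$gc_bin)
  d <- full$ratio[i_f] - half$ratio[i_h]
  # binomial SE of the nested half-sample ratio relative to the full one
  se_d <- full$ratio[i_f] * sqrt(
    pmax(1 / half$n_filtered[i_h] - 1 / full$n_filtered[i_f], 0) +
    pmax(1 / half$n_unfiltered[i_h] - 1 / full$n_unfiltered[i_f], 0))
  expect_true(all(abs(d) <= 3 * se_d + 0.02))
})
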