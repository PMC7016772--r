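test_that("genome simulation respects the GC landscape and islands", {
  spec <- genome_spec(list(list(
    name = "c1",
    segments = data.frame(length = c(2000L, 2000L), gc = c(0, 100))
  )))
  asm <- simulate_genome(spec, seed = 71)
  s <- as.character(asm[["c1"]])
  expect_true(all(strsplit(substr(s, 1, 2000), "")[[1]] %in% c("A", "T")))
  expect_true(all(strsplit(substr(s, 2001, 4000), "")[[1]] %in% c("G", "C")))

  # 100 kb at 29% target: realized 500-nt window GC concentrates at 29 +/- 3
  spec29 <- genome_spec(list(list(
    name = "c1", segments = data.frame(length = 100000L, gc = 29)
  )))
  asm29 <- simulate_genome(spec29, seed = 72)
  wt <- make_windows(asm29, list(c1 = integer(100000L)))
  sigma <- 100 * sqrt(0.29 * 0.71 / 500)        # binomial sd of window GC
  expect_lt(abs(mean(wt$gc_percent) - 29), 0.5)
  expect_true(all(abs(wt$gc_percent - 29) < 4.5 * sigma))

  # islands overwrite their intervals at their own GC
  speci <- genome_spec(list(list(
    name = "c1", segments = data.frame(length = 50000L, gc = 25),
    islands = data.frame(start = 20001L, end = 30000L, gc = 75, label = "isl")
  )))
  asmi <- simulate_genome(speci, seed = 73)
  isl_gc <- window_gc(asmi[["c1"]], start = 20001L, width = 10000L)$gc_percent
  bg_gc <- window_gc(asmi[["c1"]], start = 1L, width = 20000L)$gc_percent
  expect_gt(isl_gc, 70); expect_lt(bg_gc, 30)

  bad <- list(list(name = "c1", segments = data.frame(length = 1000L, gc = 50),
                   islands = data.frame(start = c(1L, 50L), end = c(100L, 120L),
                                        gc = 60, label = "x")))
  expect_error(genome_spec(bad), "overlapping")
})

test_that("generators are pure functions of spec and seed", {
  spec <- genome_spec(list(list(
    name = "c1", segments = data.frame(length = c(5000L, 5000L), gc = c(30, 60))
  )))
  expect_identical(as.character(simulate_genome(spec, seed = 74)),
                   as.character(simulate_genome(spec, seed = 74)))
  asm <- simulate_genome(spec, seed = 74)
  s1 <- simulate_depth(asm, bias_none(), mean_depth = 8, seed = 75)
  s2 <- simulate_depth(asm, bias_none(), mean_depth = 8, seed = 75)
  expect_identical(s1$depth_tracks, s2$depth_tracks)

  qm <- quality_model(noise_sd = 2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(asm, bias_none(), qm, n_reads = 200, seed = 76, path = f1)
  simulate_fastq(asm, bias_none(), qm, n_reads = 200, seed = 76, path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("bias models map GC to log10 efficiency at most 0", {
  q <- bias_quadratic(-0.0015, 0.165)
  g <- 0:100
  e <- bias_log_efficiency(q, g)
  expect_equal(max(e), 0, tolerance = 1e-12)     # normalized to peak 1
  expect_equal(which.max(e) - 1L, 55L)           # vertex at -b/2a
  expect_true(all(10^e > 0 & 10^e <= 1 + 1e-12))

  expect_identical(bias_log_efficiency(bias_none(), c(10, 90)), c(0, 0))

  tab <- bias_table(c(`29` = 0.1, `55` = 1.0))
  expect_equal(bias_log_efficiency(tab, c(20, 29, 41.9, 42.1, 55, 80)),
               log10(c(0.1, 0.1, 0.1, 1, 1, 1)), tolerance = 1e-12)
  expect_error(bias_table(c(`29` = 0)))          # efficiency must be positive
  expect_error(bias_table(c(`29` = 1.5)))
})

test_that("simulated depth conserves aligned bases and hits target depth", {
  asm <- gradient_assembly(seed = 77, seg_len = 10000L, gcs = c(35, 45, 55))
  sim <- simulate_depth(asm, bias_none(), mean_depth = 12, seed = 78)
  total <- sum(vapply(sim$depth_tracks, function(v) sum(as.numeric(v)), numeric(1)))
  expect_identical(total, as.numeric(sim$n_fragments) * sim$read_length)
  expect_equal(sim$n_fragments, round(12 * 30000 / 150))

  # unbiased: every populated bin's mean depth within 3 SE of the target
  wt <- make_windows(asm, sim$depth_tracks)
  prof <- split(wt$mean_depth, wt$gc_bin)
  prof <- prof[lengths(prof) >= 5]
  for (v in prof) {
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 12), 3 * se + 0.6)   # slack for edge windows
  }

  short <- Biostrings::DNAStringSet(c(tiny = "ACGT"))
  expect_warning(expect_error(
    simulate_depth(short, bias_none(), mean_depth = 5, seed = 79), "read_length"
  ), "skipped")
})

test_that("table bias drives island over-coverage at the efficiency quotient", {
  spec <- genome_spec(list(list(
    name = "c1", segments = data.frame(length = 120000L, gc = 29),
    islands = data.frame(start = c(40001L, 90001L), end = c(48000L, 98000L),
                         gc = 55, label = "rRNA-like")
  )))
  asm <- simulate_genome(spec, seed = 80)
  sim <- simulate_depth(asm, bias_table(c(`29` = 0.1, `55` = 1.0)),
                        mean_depth = 40, seed = 81)
  res <- feature_background_ratio(sim$depth_tracks, spec_islands(spec))
  expect_gt(res$ratio, 8.5)
  expect_lt(res$ratio, 11)
})

test_that("read quality degrades above the GC threshold and only there", {
  asm <- gradient_assembly(seed = 82, seg_len = 8000L, gcs = seq(40, 80, by = 10))
  flat <- simulate_fastq(asm, bias_none(),
                         quality_model(degrade_above_gc = 101, degrade_slope = 5),
                         n_reads = 2000, seed = 83)
  rqf <- read_gc_quality(flat)
  expect_identical(unique(rqf$median_phred), 37)

  deg <- simulate_fastq(asm, bias_none(),
                        quality_model(degrade_above_gc = 65, degrade_slope = 1),
                        n_reads = 4000, seed = 84)
  stats <- quality_bin_stats(read_gc_quality(deg))
  above <- stats[stats$gc_bin > 66 & stats$n_reads >= 10, ]
  expect_true(all(diff(above$median) <= 0))      # monotone decay above 65
  expect_true(all(above$median < 37))
  below <- stats[stats$gc_bin <= 64, ]
  expect_identical(unique(below$median), 37)
})
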