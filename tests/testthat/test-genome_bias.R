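test_that("normalization divides by the reference-bin mean depth", {
  wt <- toy_window_table(gc_bin = rep(c(30, 49), each = 3),
                         mean_depth = rep(c(2, 20), each = 3))
  norm <- normalize_windows(wt)
  expect_equal(norm$norm_depth, rep(c(0.1, 1), each = 3))
  expect_equal(log10(norm$norm_depth), rep(c(-1, 0), each = 3))
  expect_identical(attr(norm, "reference_bin"), 49L)
  expect_equal(attr(norm, "reference_mean"), 20)

  uni <- toy_window_table(gc_bin = c(40, 49, 49, 49, 60),
                          mean_depth = rep(7, 5))
  expect_equal(normalize_windows(uni)$norm_depth, rep(1, 5))

  # underpopulated reference bin: hard error naming viable candidates
  bad <- toy_window_table(gc_bin = c(30, 30, 30, 30, 49), mean_depth = rep(5, 5))
  expect_error(normalize_windows(bad), "30")
})

test_that("normalization matches an independent recomputation on simulated data", {
  asm <- gradient_assembly(seed = 41)
  sim <- simulate_depth(asm, bias_quadratic(-0.0015, 0.165), mean_depth = 25,
                        seed = 42)
  wt <- make_windows(asm, sim$depth_tracks)
  norm <- normalize_windows(wt)
  ref_mean <- mean(wt$mean_depth[wt$gc_bin == 49L])
  expect_equal(norm$norm_depth, wt$mean_depth / ref_mean, tolerance = 1e-12)
  # anchor: the reference bin's mean normalized coverage is 1, log10 is 0
  expect_equal(mean(norm$norm_depth[norm$gc_bin == 49L]), 1, tolerance = 1e-12)
})

test_that("bin profile applies the <3-window rule and n-1 standard deviations", {
  wt <- toy_window_table(gc_bin = c(rep(40, 3), rep(49, 3), rep(60, 2), rep(55, 4)),
                         mean_depth = c(1, 1, 1, 2, 2, 2, 9, 9, 4, 5, 6, 7))
  norm <- normalize_windows(wt)
  prof <- bin_profile(norm)
  expect_false(60 %in% prof$gc_bin)            # 2-window bin dropped
  expect_identical(prof$gc_bin, c(40L, 49L, 55L))
  b40 <- prof[prof$gc_bin == 40, ]
  expect_equal(b40$mean_norm, 0.5)
  expect_equal(b40$sd_norm, 0)
  b55 <- prof[prof$gc_bin == 55, ]
  expect_equal(b55$mean_norm, mean(c(4, 5, 6, 7) / 2))
  expect_equal(b55$sd_norm, sd(c(4, 5, 6, 7) / 2))
  expect_equal(prof$log10_mean, log10(prof$mean_norm))

  few <- toy_window_table(gc_bin = rep(c(40, 49), each = 3), mean_depth = rep(2, 6))
  expect_error(bin_profile(normalize_windows(few)), "fewer than 3")
})

test_that("per-bin means and sds match a brute-force group-by", {
  asm <- gradient_assembly(seed = 43)
  sim <- simulate_depth(asm, bias_none(), mean_depth = 10, seed = 44)
  norm <- normalize_windows(make_windows(asm, sim$depth_tracks))
  prof <- bin_profile(norm)
  for (b in prof$gc_bin) {
    v <- norm$norm_depth[norm$gc_bin == b]
    expect_equal(prof$mean_norm[prof$gc_bin == b], mean(v), tolerance = 1e-12)
    expect_equal(prof$sd_norm[prof$gc_bin == b], sd(v), tolerance = 1e-12)
  }
})

test_that("quadratic fitting interpolates exact data and honors weights", {
  g <- 35:75
  prof <- data.frame(gc_bin = g, n_windows = sample(3:30, length(g), TRUE),
                     mean_norm = 1, sd_norm = 0,
                     log10_mean = -0.002 * (g - 55)^2)
  fit <- fit_quadratic(prof)
  expect_equal(fit$a, -0.002, tolerance = 1e-9)
  expect_equal(fit$vertex_gc, 55, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- transform(prof, log10_mean = 0)
  fit0 <- fit_quadratic(flat)
  expect_equal(abs(fit0$a) + abs(fit0$b) + abs(fit0$c), 0, tolerance = 1e-12)

  one_bin <- data.frame(gc_bin = rep(50L, 3), n_windows = 5, mean_norm = 1,
                        sd_norm = 0, log10_mean = 0)
  expect_error(fit_quadratic(one_bin), "distinct")
})

test_that("weighted fit equals the closed-form normal-equations solution", {
  set.seed(45)
  g <- seq(30, 70, by = 2)
  w <- sample(3:50, length(g), TRUE)
  y <- -0.0015 * g^2 + 0.165 * g - 4 + rnorm(length(g), 0, 0.05)
  prof <- data.frame(gc_bin = g, n_windows = w, mean_norm = 10^y,
                     sd_norm = 0.1, log10_mean = y)
  fit <- fit_quadratic(prof)

  X <- cbind(g^2, g, 1)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(fit$a, beta[1L], tolerance = 1e-9)
  expect_equal(fit$b, beta[2L], tolerance = 1e-9)
  expect_equal(fit$c, beta[3L], tolerance = 1e-9)
  resid <- y - X %*% beta
  r2 <- 1 - sum(w * resid^2) / sum(w * (y - weighted.mean(y, w))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)
})

test_that("with normalization on, the fitted curve is depth-scale invariant", {
  asm <- gradient_assembly(seed = 46)
  sim <- simulate_depth(asm, bias_quadratic(-0.001, 0.11), mean_depth = 20,
                        seed = 47)
  fit_at_scale <- function(k) {
    tracks <- lapply(sim$depth_tracks, `*`, k)
    fit_quadratic(bin_profile(normalize_windows(make_windows(asm, tracks))))
  }
  f1 <- fit_at_scale(1); f5 <- fit_at_scale(5)
  expect_equal(f5$a, f1$a, tolerance = 1e-9)
  expect_equal(f5$b, f1$b, tolerance = 1e-9)
  expect_equal(f5$c, f1$c, tolerance = 1e-9)
})

test_that("feature/background ratio is the quotient of masked means", {
  tracks <- list(c1 = rep(10, 1000))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200), label = "f")
  expect_equal(feature_background_ratio(tracks, gr)$ratio, 1)

  tracks$c1[101:200] <- 80
  res <- feature_background_ratio(tracks, gr)
  expect_equal(res$ratio, 8)
  expect_identical(res$feature_bases, 100L)

  # random intervals against a brute-force mask-and-mean oracle
  set.seed(48)
  v <- rpois(5000, 20)
  starts <- sort(sample(seq(1, 4800, by = 400), 5))
  gr2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts, starts + 99),
                                label = "f")
  res2 <- feature_background_ratio(list(c1 = v), gr2)
  mask <- rep(FALSE, 5000)
  for (s in starts) mask[s:(s + 99)] <- TRUE
  expect_equal(res2$ratio, mean(v[mask]) / mean(v[!mask]), tolerance = 1e-12)

  all_feat <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  expect_error(feature_background_ratio(list(c1 = rep(1, 1000)), all_feat),
               "background")
})

test_that("amplicon read-count ratios count primary alignments per reference", {
  asm <- Biostrings::DNAStringSet(c(ampA = strrep("ACGT", 100),
                                    ampB = strrep("AATT", 100)))
  sam <- withr::local_tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             "@SQ\tSN:ampA\tLN:400", "@SQ\tSN:ampB\tLN:400")
  mk <- function(ref, n, flag = 0) {
    sprintf("r%s%03d\t%d\t%s\t1\t60\t20M\t*\t0\t0\t%s\t%s",
            ref, seq_len(n), flag, ref, strrep("A", 20), strrep("I", 20))
  }
  writeLines(c(lines, mk("ampA", 100), mk("ampB", 25), mk("ampB", 5, 256)), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE)
  res <- amplicon_read_ratio(bam, c("ampA", "ampB"))
  expect_equal(res$ratio, 4)                    # secondaries not counted
  expect_equal(unname(res$counts), c(100, 25))

  expect_equal(amplicon_read_ratio(bam, c("ampB", "ampB"))$ratio, 1)
  expect_warning(res0 <- amplicon_read_ratio(bam, c("ampA", "missing")),
                 "infinite")
  expect_identical(res0$ratio, Inf)
})
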