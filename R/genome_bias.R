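#' Normalize window coverage to a reference GC bin
#'
#' Divides every window's mean depth by the arithmetic mean depth of the
#' windows in the reference GC bin, yielding dimensionless relative coverage
#' in which the reference bin averages exactly 1. The default reference of
#' 49% GC is a bin that bacterial assemblies across a wide range of global GC
#' contents tend to populate; when it is empty or underpopulated the error
#' message lists the bins that would qualify.
#'
#' @param window_table A `window_table` from [make_windows()].
#' @param reference_bin Integer GC bin used as the normalization anchor
#'   (default 49).
#' @param min_ref_windows Minimum number of positive-depth windows required
#'   in the reference bin (default 3).
#' @return The input table with an added `norm_depth` column and attributes
#'   `reference_bin` and `reference_mean`.
#' @export
normalize_windows <- function(window_table, reference_bin = 49L,
                              min_ref_windows = 3L) {
  ref <- window_table$gc_bin == reference_bin
  n_pos <- sum(ref & window_table$mean_depth > 0)
  if (n_pos < min_ref_windows) {
    counts <- table(window_table$gc_bin[window_table$mean_depth > 0])
    candidates <- names(counts)[counts >= min_ref_windows]
    stop("reference GC bin ", reference_bin, " has ", n_pos,
         " window(s) with positive depth (need >= ", min_ref_windows, "); ",
         "bins with enough windows: ",
         if (length(candidates)) paste(candidates, collapse = ", ") else "none")
  }
  ref_mean <- mean(window_table$mean_depth[ref])
  window_table$norm_depth <- window_table$mean_depth / ref_mean
  attr(window_table, "reference_bin") <- as.integer(reference_bin)
  attr(window_table, "reference_mean") <- ref_mean
  window_table
}

#' Per-GC-bin profile of normalized coverage
#'
#' Groups normalized windows by 1%-wide GC bin and records, per bin, the
#' window count, the arithmetic mean and sample standard deviation (n-1
#' denominator) of normalized coverage, and the log10 of the mean (the mean
#' is taken in linear space and log-transformed afterwards). Bins with fewer
#' than `min_windows_per_bin` windows are discarded, as are bins whose mean
#' is zero (no log is defined for them).
#'
#' @param window_table A normalized `window_table` from [normalize_windows()].
#' @param min_windows_per_bin Minimum windows per bin (default 3).
#' @return A `data.frame` with columns `gc_bin`, `n_windows`, `mean_norm`,
#'   `sd_norm`, `log10_mean`.
#' @export
bin_profile <- function(window_table, min_windows_per_bin = 3L) {
  if (is.null(window_table$norm_depth)) {
    stop("window table has no norm_depth column; run normalize_windows() first")
  }
  sp <- split(window_table$norm_depth, window_table$gc_bin)
  prof <- data.frame(
    gc_bin = as.integer(names(sp)),
    n_windows = lengths(sp),
    mean_norm = vapply(sp, mean, numeric(1)),
    sd_norm = vapply(sp, sd, numeric(1)),
    row.names = NULL
  )
  prof <- prof[prof$n_windows >= min_windows_per_bin, , drop = FALSE]
  zero <- prof$mean_norm <= 0
  if (any(zero)) {
    warning(sum(zero), " GC bin(s) with zero mean coverage discarded")
    prof <- prof[!zero, , drop = FALSE]
  }
  prof$log10_mean <- log10(prof$mean_norm)
  prof <- prof[order(prof$gc_bin), , drop = FALSE]
  rownames(prof) <- NULL
  if (nrow(prof) < 3L) {
    stop("fewer than 3 GC bins survive (", nrow(prof),
         "); cannot characterize a bias curve")
  }
  prof
}

#' Weighted quadratic fit of the bias curve
#'
#' Fits `log10_mean ~ a*g^2 + b*g + c` over the GC bins of a profile by
#' weighted least squares, with weights equal to the number of windows per
#' bin, and reports the weighted coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` where both sums use the fitting weights and
#' `SS_tot` is taken about the weighted mean.
#'
#' @param profile A profile from [bin_profile()].
#' @return An object of class `gc_quadratic_fit`: a list with `a`, `b`, `c`,
#'   `r_squared`, `n_bins`, `total_weight`, `vertex_gc` (GC content of the
#'   curve's extremum) and `se` (standard errors of `a`, `b`, `c`).
#' @export
fit_quadratic <- function(profile) {
  stopifnot(nrow(profile) >= 3L)
  if (length(unique(profile$gc_bin)) < 3L) {
    stop("need at least 3 distinct GC bins for a quadratic fit")
  }
  g <- as.numeric(profile$gc_bin)
  fit <- lm(log10_mean ~ I(g^2) + g, data = data.frame(g = g, profile),
            weights = profile$n_windows)
  cf <- coef(fit)
  a <- unname(cf[["I(g^2)"]]); b <- unname(cf[["g"]]); c_ <- unname(cf[["(Intercept)"]])
  w <- profile$n_windows
  y <- profile$log10_mean
  ss_res <- sum(w * fit$residuals^2)
  ss_tot <- sum(w * (y - weighted.mean(y, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  se_tab <- summary(fit)$coefficients
  structure(list(
    a = a, b = b, c = c_,
    r_squared = r2,
    n_bins = nrow(profile),
    total_weight = sum(w),
    vertex_gc = if (a != 0) -b / (2 * a) else NA_real_,
    se = c(a = unname(se_tab["I(g^2)", "Std. Error"]),
           b = unname(se_tab["g", "Std. Error"]),
           c = unname(se_tab["(Intercept)", "Std. Error"]))
  ), class = "gc_quadratic_fit")
}

#' @export
print.gc_quadratic_fit <- function(x, ...) {
  cat("Quadratic GC-bias curve: log10(relative coverage) =",
      sprintf("%.4g*g^2 + %.4g*g + %.4g", x$a, x$b, x$c), "\n")
  cat(sprintf("  weighted R^2 = %.4f over %d GC bins (%d windows); optimum near %.1f%% GC\n",
              x$r_squared, x$n_bins, x$total_weight, x$vertex_gc))
  invisible(x)
}

#' Evaluate a fitted bias curve
#'
#' @param object A `gc_quadratic_fit`.
#' @param gc Numeric vector of GC percentages.
#' @param ... Ignored.
#' @return Predicted log10 relative coverage.
#' @export
predict.gc_quadratic_fit <- function(object, gc, ...) {
  object$a * gc^2 + object$b * gc + object$c
}

#' Write a fitted bias curve as JSON
#'
#' @param fit A `gc_quadratic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(a = fit$a, b = fit$b, c = fit$c, r_squared = fit$r_squared,
         n_bins = fit$n_bins, total_weight = fit$total_weight,
         vertex_gc = fit$vertex_gc),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Mean coverage of features versus background
#'
#' Mean per-base depth over the union of the supplied intervals, divided by
#' the mean per-base depth over all remaining positions of the same contigs.
#' This is the statistic behind "n-fold over-coverage of the rRNA loci":
#' in a GC-poor genome whose rRNA operons are GC-balanced islands, a strongly
#' GC-biased workflow inflates this ratio several-fold.
#'
#' @param depth_tracks Named list of per-base depth vectors.
#' @param features A `GRanges` of intervals (1-based closed, as from
#'   [read_bed_features()]).
#' @return A list with `feature_mean_depth`, `background_mean_depth`,
#'   `ratio`, `feature_bases`, `background_bases`.
#' @export
feature_background_ratio <- function(depth_tracks, features) {
  stopifnot(length(features) > 0L)
  ctgs <- unique(as.character(GenomicRanges::seqnames(features)))
  missing <- setdiff(ctgs, names(depth_tracks))
  if (length(missing)) {
    stop("no depth track for feature contig(s): ", paste(missing, collapse = ", "))
  }
  feat_sum <- 0; feat_n <- 0; bg_sum <- 0; bg_n <- 0
  red <- GenomicRanges::reduce(features)
  for (ctg in ctgs) {
    v <- depth_tracks[[ctg]]
    sub <- red[as.character(GenomicRanges::seqnames(red)) == ctg]
    if (any(GenomicRanges::end(sub) > length(v)) ||
        any(GenomicRanges::start(sub) < 1L)) {
      stop("feature interval outside contig ", ctg)
    }
    mask <- rep(FALSE, length(v))
    for (i in seq_along(sub)) {
      mask[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <- TRUE
    }
    feat_sum <- feat_sum + sum(as.numeric(v[mask]))
    feat_n <- feat_n + sum(mask)
    bg_sum <- bg_sum + sum(as.numeric(v[!mask]))
    bg_n <- bg_n + sum(!mask)
  }
  if (feat_n == 0L) stop("empty feature union")
  if (bg_n == 0L) stop("empty background (features cover their contigs entirely)")
  feat_mean <- feat_sum / feat_n
  bg_mean <- bg_sum / bg_n
  if (bg_mean <= 0) stop("background mean depth is zero")
  list(feature_mean_depth = feat_mean, background_mean_depth = bg_mean,
       ratio = feat_mean / bg_mean,
       feature_bases = as.integer(feat_n), background_bases = as.integer(bg_n))
}

#' Ratio of primary-aligned read counts between two references
#'
#' Counts reads whose primary alignment (neither secondary nor supplementary,
#' not unmapped) lands on each of exactly two reference sequences and returns
#' the fold ratio of the first over the second. Used for competitive-mapping
#' designs such as an equimolar mixture of two amplicons with contrasting GC
#' contents.
#'
#' @param bam_path Path to an indexed BAM mapped against the two references.
#' @param reference_pair Character vector of the two reference names
#'   (numerator first).
#' @return A list with `counts` (named, both references) and `ratio`; a zero
#'   denominator yields `Inf` with a warning.
#' @export
amplicon_read_ratio <- function(bam_path, reference_pair) {
  stopifnot(length(reference_pair) == 2L)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(flag = flag)
  )
  sq <- as.character(GenomicAlignments::seqnames(aln))
  counts <- setNames(
    vapply(reference_pair, function(r) sum(sq == r), numeric(1)),
    reference_pair
  )
  if (counts[[2L]] == 0) {
    warning("no primary alignments on denominator reference ",
            reference_pair[[2L]], "; ratio is infinite")
    ratio <- Inf
  } else {
    ratio <- counts[[1L]] / counts[[2L]]
  }
  list(counts = counts, ratio = ratio)
}
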