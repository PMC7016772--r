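#' Modified z-scores from the median absolute deviation
#'
#' Robust outlier scores following the standard outlier-labeling convention:
#' `M_i = 0.6745 * (x_i - median(x)) / MAD` with
#' `MAD = median(|x_i - median(x)|)`. When the MAD is zero (at least half the
#' values identical) the mean absolute deviation takes its place,
#' `M_i = (x_i - median(x)) / (1.253314 * meanAD)`, and when that is also zero
#' every score is 0. Scores are invariant under positive affine
#' transformations of the input.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Numeric vector of scores, same length as `values`.
#' @export
modified_zscore <- function(values) {
  if (length(values) == 0L) stop("modified_zscore: empty input")
  if (!all(is.finite(values))) stop("modified_zscore: non-finite input")
  med <- median(values)
  dev <- values - med
  mad_ <- median(abs(dev))
  if (mad_ > 0) {
    0.6745 * dev / mad_
  } else {
    mean_ad <- mean(abs(dev))
    if (mean_ad > 0) dev / (1.253314 * mean_ad) else rep(0, length(values))
  }
}

#' Filter contigs by length and coverage outlier status
#'
#' Genome-mode pre-filter: contigs shorter than `min_length` are dropped (the
#' default 10 kb removes plasmid-scale elements, phages and small repeat
#' contigs), explicitly excluded names are dropped (e.g. manually identified
#' plasmids), and among the survivors any contig whose mean per-base depth has
#' an absolute modified z-score above `z_threshold` is dropped as aberrantly
#' covered. A single surviving contig is always retained (its score is 0 by
#' construction). The filter is applied two-sided, catching both multi-copy
#' elements (high coverage) and contaminants or collapsed repeats (low).
#'
#' @param assembly A named `DNAStringSet`.
#' @param depth_tracks Named list of per-base depth vectors.
#' @param min_length Minimum contig length in bases (default 10000; raise it
#'   for assemblies whose 10--100 kb contigs are erratically covered).
#' @param z_threshold Absolute modified z-score cutoff (default 10).
#' @param exclude Character vector of contig names to drop unconditionally.
#' @return A list with `retained` (character vector of contig names),
#'   `stats` (per-contig `data.frame`: `contig`, `length`, `mean_depth`,
#'   `modified_z`, `action`, `reason`) and `report` (the removed rows of
#'   `stats`).
#' @export
filter_contigs <- function(assembly, depth_tracks, min_length = 10000L,
                           z_threshold = 10, exclude = character()) {
  stopifnot(length(assembly) > 0L)
  ctgs <- names(assembly)
  lens <- setNames(Biostrings::width(assembly), ctgs)
  mean_depth <- vapply(ctgs, function(ctg) mean(depth_tracks[[ctg]]), numeric(1))

  action <- setNames(rep("keep", length(ctgs)), ctgs)
  reason <- setNames(rep("", length(ctgs)), ctgs)
  action[ctgs %in% exclude] <- "drop"
  reason[ctgs %in% exclude] <- "explicitly excluded"
  short <- action == "keep" & lens < min_length
  action[short] <- "drop"
  reason[short] <- sprintf("length < %d", min_length)

  z <- setNames(rep(NA_real_, length(ctgs)), ctgs)
  surv <- ctgs[action == "keep"]
  if (length(surv) > 0L) {
    z[surv] <- modified_zscore(mean_depth[surv])
    aberrant <- surv[abs(z[surv]) > z_threshold]
    action[aberrant] <- "drop"
    reason[aberrant] <- sprintf("|modified z| > %g", z_threshold)
  }

  stats <- data.frame(contig = ctgs, length = as.integer(lens),
                      mean_depth = mean_depth, modified_z = as.numeric(z),
                      action = unname(action), reason = unname(reason),
                      stringsAsFactors = FALSE, row.names = NULL)
  retained <- ctgs[action == "keep"]
  if (length(retained) == 0L) {
    stop("no contigs survive filtering (", length(ctgs), " input contigs; ",
         sum(short), " below ", min_length, " bp, ",
         sum(ctgs %in% exclude), " excluded by name, ",
         sum(reason == sprintf("|modified z| > %g", z_threshold)),
         " coverage outliers)")
  }
  list(retained = retained, stats = stats,
       report = stats[stats$action == "drop", , drop = FALSE])
}
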