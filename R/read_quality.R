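#' Per-read GC content and median Phred quality
#'
#' For each read, computes GC percent over its unambiguous (A/C/G/T) bases
#' and the median Phred score over all its bases (the even-length median is
#' the mean of the central pair). Reads with no unambiguous bases are skipped
#' with a message reporting how many.
#'
#' @param reads A FASTQ path, or a list as returned by [read_fastq()].
#' @return A `data.frame` with one row per retained read: `gc_percent`,
#'   `gc_bin` (1%-wide, round-half-up as for windows), `median_phred`.
#' @export
read_gc_quality <- function(reads) {
  if (is.character(reads)) reads <- read_fastq(reads)
  seqs <- reads$sequences
  if (length(seqs) == 0L) stop("no reads")
  counts <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  n_unamb <- rowSums(counts)
  gc <- 100 * (counts[, "C"] + counts[, "G"]) / n_unamb
  med <- vapply(reads$qualities, function(q) median(as.numeric(q)), numeric(1))
  keep <- n_unamb > 0L
  if (any(!keep)) {
    message(sum(!keep), " read(s) with no unambiguous bases skipped")
  }
  data.frame(gc_percent = gc[keep], gc_bin = gc_bin(gc[keep]),
             median_phred = med[keep])
}

#' Boxplot statistics of read quality per GC bin
#'
#' Summarizes per-read median Phred scores within 1%-wide GC bins with the
#' five statistics of a 10th/90th-percentile-whisker boxplot. Percentiles use
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param read_quality A `data.frame` from [read_gc_quality()].
#' @return A `data.frame` with columns `gc_bin`, `n_reads`, `median`, `q1`,
#'   `q3`, `p10`, `p90`.
#' @export
quality_bin_stats <- function(read_quality) {
  sp <- split(read_quality$median_phred, read_quality$gc_bin)
  qs <- t(vapply(sp, quantile, numeric(5),
                 probs = c(0.5, 0.25, 0.75, 0.1, 0.9), names = FALSE, type = 7))
  data.frame(gc_bin = as.integer(names(sp)), n_reads = lengths(sp),
             median = qs[, 1L], q1 = qs[, 2L], q3 = qs[, 3L],
             p10 = qs[, 4L], p90 = qs[, 5L], row.names = NULL)
}

#' Effect of quality filtering on the read GC distribution
#'
#' Builds GC histograms of a quality-filtered and an unfiltered read set on
#' identical bins, converts both to proportions (each summing to 1 over its
#' own reads) and divides filtered by unfiltered per bin. Ratios far below 1
#' in a GC range mean quality filtering disproportionately removes reads of
#' that GC content. Bins present only in the filtered set are impossible;
#' bins absent from the unfiltered set have no defined ratio and are omitted.
#' The `abundant` flag marks bins carrying at least 0.1% of the unfiltered
#' reads, the conventional cut below which ratios are too noisy to interpret.
#'
#' @param filtered Quality-filtered reads: FASTQ path, [read_fastq()] list,
#'   or [read_gc_quality()] data.frame.
#' @param unfiltered Unfiltered reads, same forms.
#' @param bin_width GC bin width in percentage points (default 1).
#' @return A `data.frame` with columns `gc_bin` (bin center),
#'   `n_filtered`, `n_unfiltered`, `proportion_filtered`,
#'   `proportion_unfiltered`, `ratio`, `abundant`.
#' @export
filter_proportion_ratios <- function(filtered, unfiltered, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  as_rq <- function(x) {
    if (is.data.frame(x)) x else read_gc_quality(x)
  }
  f <- as_rq(filtered); u <- as_rq(unfiltered)
  if (nrow(f) == 0L || nrow(u) == 0L) stop("both read sets must be non-empty")
  binify <- function(gc) as.integer(floor(gc / bin_width + 0.5))
  fb <- binify(f$gc_percent); ub <- binify(u$gc_percent)
  bins <- sort(unique(ub))
  n_f <- vapply(bins, function(b) sum(fb == b), numeric(1))
  n_u <- vapply(bins, function(b) sum(ub == b), numeric(1))
  p_f <- n_f / nrow(f)
  p_u <- n_u / nrow(u)
  data.frame(
    gc_bin = bins * bin_width,
    n_filtered = n_f, n_unfiltered = n_u,
    proportion_filtered = p_f, proportion_unfiltered = p_u,
    ratio = p_f / p_u,
    abundant = p_u >= 0.001
  )
}

#' Subset reads by median Phred score
#'
#' A minimal quality filter for simulation-driven comparisons: keeps reads
#' whose median Phred score is at least `min_median`. Real datasets should be
#' filtered upstream with a dedicated trimmer; this exists so that the
#' filtered/unfiltered comparison of [filter_proportion_ratios()] can be
#' exercised end-to-end on simulated reads.
#'
#' @param reads A list as returned by [read_fastq()].
#' @param min_median Minimum per-read median Phred score.
#' @return A list of the same shape containing the retained reads.
#' @export
filter_reads_by_median_quality <- function(reads, min_median) {
  med <- vapply(reads$qualities, function(q) median(as.numeric(q)), numeric(1))
  keep <- med >= min_median
  list(sequences = reads$sequences[keep], qualities = reads$qualities[keep])
}
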