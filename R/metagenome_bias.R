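#' Per-contig mean coverage by GC bin
#'
#' Within each contig, averages the (raw, un-normalized) window depths per
#' 1%-wide GC bin. Metagenome mode normalizes within contigs via ratios, so
#' no cross-contig normalization or coverage-based contig filtering is
#' applied here: each contig is treated as an independent genetic element.
#' Bins whose mean depth is zero are excluded so they never enter ratio
#' formation as zero denominators.
#'
#' @param window_table A `window_table` from [make_windows()] (built from
#'   contigs that already passed the length cutoff).
#' @param min_windows_per_bin Minimum windows per (contig, bin) cell
#'   (default 1; metagenome contigs are short enough that demanding more
#'   discards most of the signal).
#' @return A named list (one element per contig) of named numeric vectors
#'   mapping GC bin to mean depth.
#' @export
contig_bin_means <- function(window_table, min_windows_per_bin = 1L) {
  sp <- split(window_table[, c("gc_bin", "mean_depth")], window_table$contig)
  out <- lapply(sp, function(d) {
    bins <- split(d$mean_depth, d$gc_bin)
    bins <- bins[lengths(bins) >= min_windows_per_bin]
    m <- vapply(bins, mean, numeric(1))
    m[m > 0]
  })
  out[order(names(out))]
}

#' Pairwise GC-bin coverage-ratio matrix
#'
#' For every ordered pair of GC bins (i, j), computes within each contig
#' containing both bins the ratio of the contig's mean coverage in bin i to
#' its mean coverage in bin j, averages those ratios across the contributing
#' contigs, and stores the log10 of the average together with the contig
#' count. Entries above 0 mean windows of the numerator's GC content are
#' better covered than windows of the denominator's. With the default
#' arithmetic averaging the matrix is only antisymmetric when a single contig
#' contributes (the AM-GM inequality forces `M[i,j] + M[j,i] >= 0`
#' otherwise); `geometric = TRUE` averages in log space instead, which is
#' exactly antisymmetric at the cost of a less literal "average ratio".
#'
#' @param bin_means Output of [contig_bin_means()].
#' @param geometric Average ratios geometrically instead of arithmetically.
#' @return An object of class `gc_ratio_matrix`: a list with
#'   `log10_mean_ratio` and `n_contigs`, both 101 x 101 matrices indexed by
#'   GC bin 0..100 (dimnames give the bins; absent pairs are `NA` /
#'   0 contigs), and the `geometric` flag.
#' @export
ratio_matrix <- function(bin_means, geometric = FALSE) {
  bins <- 0:100
  acc <- matrix(0, 101L, 101L, dimnames = list(bins, bins))
  n <- matrix(0L, 101L, 101L, dimnames = list(bins, bins))
  usable <- 0L
  for (m in bin_means) {
    if (length(m) < 1L) next
    idx <- as.integer(names(m)) + 1L
    r <- outer(m, m, "/")
    acc[idx, idx] <- acc[idx, idx] + (if (geometric) log10(r) else r)
    n[idx, idx] <- n[idx, idx] + 1L
    if (length(m) >= 2L) usable <- usable + 1L
  }
  if (usable == 0L) {
    stop("no contig contains two populated GC bins; cannot form ratios")
  }
  log10_mean <- matrix(NA_real_, 101L, 101L, dimnames = list(bins, bins))
  has <- n > 0L
  log10_mean[has] <- if (geometric) acc[has] / n[has] else log10(acc[has] / n[has])
  structure(list(log10_mean_ratio = log10_mean, n_contigs = n,
                 geometric = geometric),
            class = "gc_ratio_matrix")
}

#' @export
print.gc_ratio_matrix <- function(x, ...) {
  present <- which(x$n_contigs > 0L, arr.ind = TRUE)
  bins <- sort(unique(c(present[, 1L], present[, 2L]))) - 1L
  cat("GC-bin coverage-ratio matrix (", if (x$geometric) "geometric" else "arithmetic",
      " cross-contig averaging)\n", sep = "")
  cat("  populated GC bins: ", length(bins),
      if (length(bins)) paste0(" (", min(bins), "..", max(bins), ")"),
      "; max contigs per pair: ", max(x$n_contigs), "\n", sep = "")
  invisible(x)
}

#' Export a ratio matrix as long-format TSV
#'
#' One row per ordered bin pair with at least one contributing contig;
#' columns `numerator_gc`, `denominator_gc`, `log10_mean_ratio`,
#' `n_contigs`. Rows are sorted by numerator then denominator bin, so the
#' export is deterministic and re-importable with [read_ratio_matrix()].
#'
#' @param matrix A `gc_ratio_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_ratio_matrix <- function(matrix, path) {
  idx <- which(matrix$n_contigs > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ratio matrix")
  tab <- data.frame(
    numerator_gc = idx[, 1L] - 1L,
    denominator_gc = idx[, 2L] - 1L,
    log10_mean_ratio = matrix$log10_mean_ratio[idx],
    n_contigs = matrix$n_contigs[idx]
  )
  tab <- tab[order(tab$numerator_gc, tab$denominator_gc), , drop = FALSE]
  write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Re-import a ratio matrix exported by [export_ratio_matrix()]
#'
#' @param path Path to the long-format TSV.
#' @param geometric Flag recorded on the rebuilt object.
#' @return A `gc_ratio_matrix`.
#' @export
read_ratio_matrix <- function(path, geometric = FALSE) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  bins <- 0:100
  log10_mean <- matrix(NA_real_, 101L, 101L, dimnames = list(bins, bins))
  n <- matrix(0L, 101L, 101L, dimnames = list(bins, bins))
  idx <- cbind(tab$numerator_gc + 1L, tab$denominator_gc + 1L)
  log10_mean[idx] <- tab$log10_mean_ratio
  n[idx] <- tab$n_contigs
  structure(list(log10_mean_ratio = log10_mean, n_contigs = n,
                 geometric = geometric),
            class = "gc_ratio_matrix")
}
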