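# Figures are derived views of the TSV outputs; the numeric tables are the
# contract and every plot is regenerable from them.

#' Dot plot of the GC-bias profile
#'
#' Normalized relative coverage (log10 scale) against GC bin, with +/- 1
#' standard deviation error bars, point shading by the log of the window
#' count per bin, an optional vertical marker at the assembly's mean GC and a
#' dashed horizontal line at the average normalized coverage. The fitted
#' quadratic, if given, is drawn through the bins.
#'
#' @param profile A profile from [bin_profile()].
#' @param fit Optional `gc_quadratic_fit`.
#' @param mean_gc Optional mean GC percent of the assembly.
#' @return A ggplot object.
#' @export
plot_bias_profile <- function(profile, fit = NULL, mean_gc = NULL) {
  profile$lo <- pmax(profile$mean_norm - profile$sd_norm,
                     min(profile$mean_norm) * 1e-2)
  profile$hi <- profile$mean_norm + profile$sd_norm
  avg <- weighted.mean(profile$mean_norm, profile$n_windows)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$gc_bin, y = .data$mean_norm)) +
    ggplot2::geom_hline(yintercept = avg, linetype = "dashed", colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.4, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(alpha = log10(.data$n_windows)),
                        colour = "blue", size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_alpha_continuous(range = c(0.25, 1), guide = "none") +
    ggplot2::labs(x = "GC content of window (%)",
                  y = "Normalized relative coverage",
                  title = "GC-dependent coverage bias") +
    ggplot2::theme_bw()
  if (!is.null(mean_gc)) {
    p <- p + ggplot2::geom_vline(xintercept = mean_gc, colour = "darkgreen")
  }
  if (!is.null(fit)) {
    grid <- data.frame(gc_bin = seq(min(profile$gc_bin), max(profile$gc_bin),
                                    length.out = 200))
    grid$mean_norm <- 10^predict(fit, grid$gc_bin)
    p <- p + ggplot2::geom_line(data = grid, colour = "black")
  }
  p
}

#' Heatmap of the pairwise GC-bin coverage-ratio matrix
#'
#' Static replacement for a rotating 3D rendering: log10 mean coverage ratio
#' per ordered bin pair, with tile opacity scaled by the number of
#' supporting contigs.
#'
#' @param matrix A `gc_ratio_matrix`.
#' @return A ggplot object.
#' @export
plot_ratio_heatmap <- function(matrix) {
  idx <- which(matrix$n_contigs > 0L, arr.ind = TRUE)
  tab <- data.frame(numerator_gc = idx[, 1L] - 1L,
                    denominator_gc = idx[, 2L] - 1L,
                    log10_ratio = matrix$log10_mean_ratio[idx],
                    n_contigs = matrix$n_contigs[idx])
  lim <- max(abs(tab$log10_ratio))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$denominator_gc,
                                    y = .data$numerator_gc,
                                    fill = .data$log10_ratio,
                                    alpha = log10(.data$n_contigs + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim),
                                  name = "log10 ratio") +
    ggplot2::scale_alpha_continuous(range = c(0.3, 1), guide = "none") +
    ggplot2::labs(x = "Denominator GC bin (%)", y = "Numerator GC bin (%)",
                  title = "Within-contig GC-bin coverage ratios") +
    ggplot2::theme_bw()
}

#' Boxplot-style summary of read quality per GC bin
#'
#' Median, interquartile box and 10th--90th percentile whiskers of per-read
#' median Phred scores in 1%-wide GC bins.
#'
#' @param stats Output of [quality_bin_stats()].
#' @return A ggplot object.
#' @export
plot_quality_by_gc <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$gc_bin)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                           width = 0.3, colour = "grey40") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           fill = "lightsteelblue", width = 0.8,
                           colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "Read GC content (%)", y = "Median Phred score per read",
                  title = "Read quality versus GC content") +
    ggplot2::theme_bw()
}

#' Bar plot of quality-filtered / unfiltered proportion ratios
#'
#' Bars below 1 mark GC contents disproportionately removed by quality
#' filtering. Bins holding at least 0.1% of the unfiltered reads are drawn
#' in dark blue; rarer bins fade out.
#'
#' @param ratios Output of [filter_proportion_ratios()].
#' @return A ggplot object.
#' @export
plot_filter_ratios <- function(ratios) {
  ratios$emphasis <- pmin(1, ratios$proportion_unfiltered / 0.001)
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$gc_bin, y = .data$ratio,
                                       alpha = .data$emphasis)) +
    ggplot2::geom_col(fill = "darkblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = "Read GC content (%)",
                  y = "Proportion filtered / proportion unfiltered",
                  title = "Effect of quality filtering by GC content") +
    ggplot2::theme_bw()
}
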