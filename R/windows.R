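#' GC content of a single window
#'
#' GC percent is computed over the unambiguous (A/C/G/T) bases only. A window
#' is valid only when at least `min_unambiguous_frac` of its bases are
#' unambiguous; invalid windows carry `gc_percent = NA` rather than raising an
#' error, so that N-rich stretches of draft assemblies are silently excluded
#' downstream instead of distorting the GC axis.
#'
#' @param sequence A `DNAString` (or single `character`).
#' @param start 1-based start of the window within `sequence`.
#' @param width Window width in bases; the window must fit in the sequence.
#' @param min_unambiguous_frac Minimum fraction of A/C/G/T bases (default 0.9).
#' @return A list with `gc_percent` (`NA` for invalid windows) and
#'   `n_unambiguous`.
#' @export
window_gc <- function(sequence, start = 1L, width = length(sequence),
                      min_unambiguous_frac = 0.9) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  stopifnot(start >= 1L, start + width - 1L <= length(sequence))
  win <- Biostrings::subseq(sequence, start = start, width = width)
  counts <- Biostrings::letterFrequency(win, letters = c("A", "C", "G", "T"))
  n_unamb <- sum(counts)
  gc <- if (n_unamb == 0L || n_unamb / width < min_unambiguous_frac) {
    NA_real_
  } else {
    100 * (counts[["C"]] + counts[["G"]]) / n_unamb
  }
  list(gc_percent = gc, n_unambiguous = as.integer(n_unamb))
}

#' Assign a GC percentage to a 1%-wide bin
#'
#' Bins are centered on integers and closed with round-half-up, so that a
#' window at exactly 48.5% GC lands in bin 49. Centering makes the reference
#' bin of [normalize_windows()] contain the windows closest to its nominal GC.
#'
#' @param gc_percent Numeric vector of GC percentages (0--100).
#' @return Integer bin labels 0--100.
#' @export
gc_bin <- function(gc_percent) {
  as.integer(floor(gc_percent + 0.5))
}

#' Tile an assembly into GC/coverage windows
#'
#' Computes local GC content and mean read depth in fixed-width windows. Each
#' contig is tiled from its first base with the given stride; a trailing
#' partial window is discarded, and a contig shorter than one window yields no
#' windows (with a message). Windows whose unambiguous-base fraction falls
#' below `min_unambiguous_frac` are excluded; the number excluded is kept in
#' the `n_invalid_gc` attribute.
#'
#' @param assembly A named `DNAStringSet`.
#' @param depth_tracks Named list of per-base depth vectors covering (at
#'   least) every assembly contig, as from [read_depth_tsv()] or
#'   [depth_from_alignments()].
#' @param width Window width in bases (default 500).
#' @param stride Distance between window starts (default `width`,
#'   i.e. non-overlapping windows).
#' @param min_unambiguous_frac Minimum A/C/G/T fraction per window.
#' @return A `data.frame` of class `window_table` with columns `contig`,
#'   `start` (0-based), `end` (exclusive), `gc_percent`, `gc_bin`,
#'   `n_unambiguous`, `mean_depth`, and attributes `window_width`, `stride`
#'   and `n_invalid_gc`.
#' @export
make_windows <- function(assembly, depth_tracks, width = 500L,
                         stride = width, min_unambiguous_frac = 0.9) {
  stopifnot(width >= 1L, stride >= 1L)
  missing <- setdiff(names(assembly), names(depth_tracks))
  if (length(missing)) {
    stop("no depth track for contig(s): ", paste(missing, collapse = ", "))
  }
  per_contig <- lapply(names(assembly), function(ctg) {
    seq <- assembly[[ctg]]
    len <- length(seq)
    if (len < width) {
      message("contig ", ctg, " (", len, " bp) shorter than window width ",
              width, "; no windows emitted")
      return(NULL)
    }
    starts1 <- seq.int(1L, len - width + 1L, by = stride)
    if (stride == 1L) {
      counts <- Biostrings::letterFrequencyInSlidingView(
        seq, view.width = width, letters = c("A", "C", "G", "T")
      )
    } else {
      views <- Biostrings::Views(seq, start = starts1, width = width)
      counts <- Biostrings::letterFrequency(views, letters = c("A", "C", "G", "T"))
    }
    n_unamb <- as.integer(rowSums(counts))
    gc <- 100 * (counts[, "C"] + counts[, "G"]) / n_unamb
    gc[n_unamb == 0L | n_unamb / width < min_unambiguous_frac] <- NA_real_
    dep <- depth_tracks[[ctg]]
    if (length(dep) != len) {
      stop("depth track length for ", ctg, " (", length(dep),
           ") does not match contig length (", len, ")")
    }
    cs <- c(0, cumsum(as.numeric(dep)))
    mean_depth <- (cs[starts1 + width] - cs[starts1]) / width
    data.frame(
      contig = ctg,
      start = starts1 - 1L,
      end = starts1 - 1L + width,
      gc_percent = as.numeric(gc),
      gc_bin = gc_bin(gc),
      n_unambiguous = n_unamb,
      mean_depth = mean_depth,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_contig)
  if (is.null(tab)) {
    tab <- data.frame(contig = character(), start = integer(), end = integer(),
                      gc_percent = numeric(), gc_bin = integer(),
                      n_unambiguous = integer(), mean_depth = numeric())
  }
  n_invalid <- sum(is.na(tab$gc_percent))
  tab <- tab[!is.na(tab$gc_percent), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            window_width = as.integer(width),
            stride = as.integer(stride),
            n_invalid_gc = n_invalid,
            class = c("window_table", "data.frame"))
}

#' @export
print.window_table <- function(x, ...) {
  cat("GC/coverage window table: ", nrow(x), " windows, width ",
      attr(x, "window_width"), " nt, stride ", attr(x, "stride"), " nt",
      if (!is.null(attr(x, "reference_mean")))
        paste0(", normalized (reference bin ", attr(x, "reference_bin"),
               ", mean depth ", signif(attr(x, "reference_mean"), 6), ")"),
      "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Fine-grained GC/coverage track for plotting
#'
#' Computes the stride-1 sliding-window track used for per-base coverage/GC
#' plots (e.g. 50-nt windows along a chromosome) and returns it as a plain
#' table suitable for TSV export.
#'
#' @inheritParams make_windows
#' @param width Window width in bases (default 50).
#' @return A `data.frame` with columns `contig`, `start` (0-based),
#'   `gc_percent`, `mean_depth`.
#' @export
per_base_track <- function(assembly, depth_tracks, width = 50L,
                           min_unambiguous_frac = 0.9) {
  wt <- make_windows(assembly, depth_tracks, width = width, stride = 1L,
                     min_unambiguous_frac = min_unambiguous_frac)
  data.frame(contig = wt$contig, start = wt$start,
             gc_percent = wt$gc_percent, mean_depth = wt$mean_depth)
}

#' Write a window table (or any plain table) as TSV
#'
#' Deterministic column order and Unix line termination.
#'
#' @param tab A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}
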