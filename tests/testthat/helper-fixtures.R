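# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# A small assembly with a GC gradient, handy wherever windows are needed.
# The default landscape includes a 49% segment long enough that the reference
# GC bin is always well populated at 500-nt windows.
gradient_assembly <- function(seed = 11, seg_len = 20000L,
                              gcs = seq(29, 65, by = 4)) {
  spec <- genome_spec(list(list(
    name = "ctg1",
    segments = data.frame(length = rep(seg_len, length(gcs)), gc = gcs)
  )))
  simulate_genome(spec, seed = seed)
}

# Independent brute-force recomputation of make_windows: character-level GC
# counting and explicit per-base depth summation.
naive_windows <- function(assembly, depth_tracks, width, stride,
                          min_unambiguous_frac = 0.9) {
  rows <- list()
  for (ctg in names(assembly)) {
    s <- as.character(assembly[[ctg]])
    len <- nchar(s)
    if (len < width) next
    dep <- depth_tracks[[ctg]]
    for (start1 in seq(1L, len - width + 1L, by = stride)) {
      win <- strsplit(substr(s, start1, start1 + width - 1L), "")[[1L]]
      n_unamb <- sum(win %in% c("A", "C", "G", "T"))
      if (n_unamb == 0L || n_unamb / width < min_unambiguous_frac) next
      gc <- 100 * sum(win %in% c("G", "C")) / n_unamb
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = start1 - 1L,
        gc_percent = gc, gc_bin = as.integer(floor(gc + 0.5)),
        mean_depth = sum(dep[start1:(start1 + width - 1L)]) / width
      )
    }
  }
  do.call(rbind, rows)
}

# Random per-contig GC-bin mean maps for ratio-matrix property tests.
random_bin_means <- function(n_contigs, max_bins = 6L) {
  lapply(seq_len(n_contigs), function(i) {
    k <- sample(1:max_bins, 1L)
    bins <- sort(sample(20:80, k))
    setNames(runif(k, 0.5, 50), bins)
  })
}

# Brute-force ratio matrix: explicit triple loop over (contig, i, j).
naive_ratio_matrix <- function(bin_means, geometric = FALSE) {
  sums <- matrix(0, 101, 101)
  n <- matrix(0L, 101, 101)
  for (m in bin_means) {
    bins <- as.integer(names(m))
    for (i in seq_along(bins)) {
      for (j in seq_along(bins)) {
        r <- m[[i]] / m[[j]]
        sums[bins[i] + 1L, bins[j] + 1L] <-
          sums[bins[i] + 1L, bins[j] + 1L] + (if (geometric) log10(r) else r)
        n[bins[i] + 1L, bins[j] + 1L] <- n[bins[i] + 1L, bins[j] + 1L] + 1L
      }
    }
  }
  out <- matrix(NA_real_, 101, 101)
  has <- n > 0L
  out[has] <- if (geometric) sums[has] / n[has] else log10(sums[has] / n[has])
  list(log10_mean_ratio = out, n_contigs = n)
}

# A minimal window table straight from numbers (bypasses sequence handling)
# for normalization/binning unit tests.
toy_window_table <- function(gc_bin, mean_depth, contig = "c1") {
  structure(
    data.frame(contig = contig, start = seq_along(gc_bin) * 500L - 500L,
               end = seq_along(gc_bin) * 500L,
               gc_percent = as.numeric(gc_bin), gc_bin = as.integer(gc_bin),
               n_unambiguous = 500L, mean_depth = mean_depth),
    window_width = 500L, stride = 500L, n_invalid_gc = 0L,
    class = c("window_table", "data.frame")
  )
}
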