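# Synthetic data with known injected GC bias: genomes with a controlled GC
# landscape, depth tracks / alignments sampled with a GC-dependent fragment
# efficiency, and reads whose quality degrades above a GC threshold.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)  # R's default Mersenne-Twister: named, seedable, portable
  force(expr)
}

#' Specify a synthetic genome
#'
#' A genome specification is a list of contigs; each contig is a list with a
#' `name`, a `segments` data.frame (`length` in bases, target `gc` percent)
#' describing its locally varying GC landscape, and optionally an `islands`
#' data.frame (`start`, `end` 1-based closed, target `gc`, `label`) of
#' intervals rewritten at their own GC, emulating e.g. GC-balanced rRNA-like
#' islands inside a GC-poor chromosome.
#'
#' @param contigs List of contig specifications as above.
#' @return A validated object of class `genome_spec`.
#' @export
genome_spec <- function(contigs) {
  stopifnot(length(contigs) > 0L)
  for (ctg in contigs) {
    stopifnot(is.character(ctg$name), nrow(ctg$segments) >= 1L,
              all(ctg$segments$length >= 1L),
              all(ctg$segments$gc >= 0), all(ctg$segments$gc <= 100))
    len <- sum(ctg$segments$length)
    isl <- ctg$islands
    if (!is.null(isl) && nrow(isl) > 0L) {
      stopifnot(all(isl$start >= 1L), all(isl$end <= len),
                all(isl$start <= isl$end),
                all(isl$gc >= 0), all(isl$gc <= 100))
      ir <- IRanges::IRanges(isl$start, isl$end)
      if (sum(IRanges::width(IRanges::reduce(ir))) < sum(IRanges::width(ir))) {
        stop("overlapping islands on contig ", ctg$name)
      }
    }
  }
  if (anyDuplicated(vapply(contigs, `[[`, character(1), "name"))) {
    stop("duplicate contig names in genome spec")
  }
  structure(list(contigs = contigs), class = "genome_spec")
}

#' Island intervals of a genome spec as GRanges
#'
#' @param spec A `genome_spec`.
#' @return A `GRanges` with `label` and target `gc` columns (empty if the
#'   spec has no islands).
#' @export
spec_islands <- function(spec) {
  pieces <- lapply(spec$contigs, function(ctg) {
    isl <- ctg$islands
    if (is.null(isl) || nrow(isl) == 0L) return(NULL)
    GenomicRanges::GRanges(
      seqnames = ctg$name,
      ranges = IRanges::IRanges(isl$start, isl$end),
      label = if (!is.null(isl$label)) isl$label else "island",
      gc = isl$gc
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(GenomicRanges::GRanges())
  do.call(c, pieces)
}

random_bases <- function(n, gc) {
  p_gc <- gc / 100
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2, T = (1 - p_gc) / 2)
  c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = probs)]
}

#' Simulate a genome with a controlled GC landscape
#'
#' Bases are drawn i.i.d. per segment with `P(G or C)` equal to the segment's
#' target GC (split evenly between G and C, and between A and T); island
#' intervals are then overwritten with bases drawn at their own target GC.
#' Identical `(spec, seed)` give byte-identical output.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    seqs <- vapply(spec$contigs, function(ctg) {
      bases <- unlist(lapply(seq_len(nrow(ctg$segments)), function(i) {
        random_bases(ctg$segments$length[i], ctg$segments$gc[i])
      }), use.names = FALSE)
      isl <- ctg$islands
      if (!is.null(isl) && nrow(isl) > 0L) {
        for (i in seq_len(nrow(isl))) {
          span <- isl$start[i]:isl$end[i]
          bases[span] <- random_bases(length(span), isl$gc[i])
        }
      }
      paste(bases, collapse = "")
    }, character(1))
    names(seqs) <- vapply(spec$contigs, `[[`, character(1), "name")
    Biostrings::DNAStringSet(seqs)
  })
}

#' GC-bias models for the simulator
#'
#' A bias model maps a fragment's GC percent to a log10 relative sampling
#' efficiency `e(gc) <= 0` (efficiency `10^e` in (0, 1]); fragments are then
#' sampled proportionally to efficiency. Three kinds are available:
#' `bias_none()` is perfectly even sequencing; `bias_quadratic(a, b)` uses
#' `e(g) = a*g^2 + b*g + c` with `c` chosen so the maximum efficiency over
#' 0--100% GC is exactly 1, the shape that dome-like bias profiles of
#' PCR-based short-read workflows follow; `bias_table(efficiency)` takes an
#' explicit per-GC-bin efficiency map (unlisted bins use the nearest listed
#' bin).
#'
#' @param a,b Quadratic coefficients in log10-efficiency space.
#' @param efficiency Named numeric vector: names are GC bins (0--100),
#'   values are relative efficiencies in (0, 1].
#' @return An object of class `gc_bias_model`.
#' @export
bias_quadratic <- function(a, b) {
  cands <- c(0, 100)
  if (a < 0) {
    v <- -b / (2 * a)
    if (v >= 0 && v <= 100) cands <- c(cands, v)
  }
  c_ <- -max(a * cands^2 + b * cands)
  structure(list(kind = "quadratic", a = a, b = b, c = c_),
            class = "gc_bias_model")
}

#' @rdname bias_quadratic
#' @export
bias_none <- function() {
  structure(list(kind = "none"), class = "gc_bias_model")
}

#' @rdname bias_quadratic
#' @export
bias_table <- function(efficiency) {
  stopifnot(length(efficiency) >= 1L, all(efficiency > 0), all(efficiency <= 1),
            !is.null(names(efficiency)))
  bins <- as.numeric(names(efficiency))
  stopifnot(!any(is.na(bins)), all(bins >= 0), all(bins <= 100))
  o <- order(bins)
  structure(list(kind = "table", bins = bins[o],
                 log10_eff = log10(unname(efficiency)[o])),
            class = "gc_bias_model")
}

#' Log10 relative sampling efficiency of a bias model
#'
#' @param model A `gc_bias_model`.
#' @param gc Numeric vector of GC percentages.
#' @return Numeric vector of log10 efficiencies (all `<= 0`).
#' @export
bias_log_efficiency <- function(model, gc) {
  stopifnot(inherits(model, "gc_bias_model"))
  switch(model$kind,
    none = rep(0, length(gc)),
    quadratic = model$a * gc^2 + model$b * gc + model$c,
    table = {
      mids <- head(model$bins, -1L) + diff(model$bins) / 2
      model$log10_eff[findInterval(gc, mids) + 1L]
    },
    stop("unknown bias model kind: ", model$kind)
  )
}

# Per-contig fragment-start weights: 10^e(GC of the read_length-wide fragment
# starting there); fragments with no unambiguous base get weight 0.
fragment_weights <- function(seq, bias_model, read_length) {
  counts <- Biostrings::letterFrequencyInSlidingView(
    seq, view.width = read_length, letters = c("A", "C", "G", "T")
  )
  n_unamb <- rowSums(counts)
  gc <- 100 * (counts[, "C"] + counts[, "G"]) / n_unamb
  w <- 10^bias_log_efficiency(bias_model, gc)
  w[n_unamb == 0L] <- 0
  w
}

# Draw n fragment start positions across contigs with probability
# proportional to weight. Assumes the RNG is already seeded by the caller.
sample_fragments <- function(assembly, bias_model, n, read_length) {
  usable <- names(assembly)[Biostrings::width(assembly) >= read_length]
  skipped <- setdiff(names(assembly), usable)
  if (length(skipped)) {
    warning("contig(s) shorter than read length skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(usable) == 0L) stop("no contig is at least read_length long")
  wl <- lapply(usable, function(ctg) {
    fragment_weights(assembly[[ctg]], bias_model, read_length)
  })
  w <- unlist(wl, use.names = FALSE)
  if (all(w == 0)) stop("all fragment weights are zero")
  cw <- cumsum(w)
  pick <- findInterval(runif(n) * cw[length(cw)], cw, left.open = TRUE) + 1L
  offsets <- cumsum(c(0L, head(lengths(wl), -1L)))
  ctg_idx <- findInterval(pick - 1L, offsets, left.open = FALSE)
  data.frame(contig = usable[ctg_idx],
             start = pick - offsets[ctg_idx],  # 1-based within contig
             stringsAsFactors = FALSE)
}

#' Simulate GC-biased sequencing depth
#'
#' Places `round(mean_depth * genome_length / read_length)` single-end
#' fragments of fixed length on the assembly, sampling start positions with
#' probability proportional to `10^e(gc)` where `gc` is each candidate
#' fragment's GC percent under `bias_model`, and accumulates per-base depth.
#' With `bias_none()` the expected depth is `mean_depth` everywhere. The bias
#' acts on fragment GC -- the library-preparation scale at which selection
#' happens -- so window-level analyses observe its smoothed consequence.
#'
#' @param assembly A named `DNAStringSet`.
#' @param bias_model A `gc_bias_model` (default [bias_none()]).
#' @param mean_depth Target unbiased mean depth (reads per base).
#' @param read_length Fragment/read length in bases (default 150).
#' @param seed Integer seed.
#' @param alignments Keep the individual fragment placements (needed to
#'   write SAM/BAM with [write_sam()])?
#' @return A list with `depth_tracks` (named list of integer vectors),
#'   `n_fragments`, `read_length`, `bias_model`, and (when requested)
#'   `fragments` (a data.frame of `contig`, 1-based `start`).
#' @export
simulate_depth <- function(assembly, bias_model = bias_none(), mean_depth,
                           read_length = 150L, seed, alignments = FALSE) {
  stopifnot(mean_depth > 0)
  with_seed(seed, {
    usable_len <- sum(Biostrings::width(assembly)[
      Biostrings::width(assembly) >= read_length])
    n_frags <- as.integer(round(mean_depth * usable_len / read_length))
    frags <- sample_fragments(assembly, bias_model, n_frags, read_length)
    tracks <- lapply(names(assembly), function(ctg) {
      len <- length(assembly[[ctg]])
      n_starts <- len - read_length + 1L
      if (n_starts < 1L) return(integer(len))
      counts <- tabulate(frags$start[frags$contig == ctg], nbins = n_starts)
      cs <- cumsum(c(counts, rep(0L, read_length - 1L)))
      as.integer(cs - c(rep(0L, read_length), head(cs, len - read_length)))
    })
    names(tracks) <- names(assembly)
    out <- list(depth_tracks = tracks, n_fragments = n_frags,
                read_length = as.integer(read_length), bias_model = bias_model)
    if (alignments) out$fragments <- frags[order(frags$contig, frags$start), ]
    out
  })
}

#' Write simulated fragments as SAM (and optionally BAM)
#'
#' Emits one primary alignment per simulated fragment (flag 0, full-match
#' CIGAR). With `bam = TRUE` the SAM is converted to a coordinate-sorted,
#' indexed BAM suitable for [depth_from_alignments()].
#'
#' @param sim Output of [simulate_depth()] with `alignments = TRUE`.
#' @param assembly The assembly the fragments were sampled from.
#' @param path Output SAM path.
#' @param bam Also produce `<path without .sam>.bam` plus index?
#' @return The SAM path (or BAM path when `bam = TRUE`), invisibly.
#' @export
write_sam <- function(sim, assembly, path, bam = FALSE) {
  if (is.null(sim$fragments)) {
    stop("simulation was run without alignments = TRUE")
  }
  rl <- sim$read_length
  con <- file(path, open = "wt")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ctg in names(assembly)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, length(assembly[[ctg]])), con)
  }
  frags <- sim$fragments
  qual <- strrep("I", rl)
  for (ctg in unique(frags$contig)) {
    starts <- frags$start[frags$contig == ctg]
    seqs <- as.character(Biostrings::Views(assembly[[ctg]], start = starts,
                                           width = rl))
    writeLines(sprintf("frag_%s_%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       ctg, seq_along(starts), ctg, starts, rl, seqs, qual), con)
  }
  close(con)
  if (!bam) return(invisible(path))
  dest <- sub("\\.sam$", "", path)
  bam_path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                               indexDestination = TRUE)
  invisible(bam_path)
}

#' Read-quality model for the simulator
#'
#' Reads receive a single Phred score applied to all their bases:
#' `base_phred` up to `degrade_above_gc` percent GC, dropping by
#' `degrade_slope` Phred units per GC percentage point beyond it, plus
#' Gaussian noise, clipped to [2, 41]. This reproduces the empirical pattern
#' of short-read chemistry calling high-GC reads with lower confidence.
#'
#' @param base_phred Plateau Phred score (default 37).
#' @param degrade_above_gc GC percent above which quality degrades
#'   (default 65; use > 100 for no degradation).
#' @param degrade_slope Phred units lost per GC percent above the threshold.
#' @param noise_sd Standard deviation of per-read Gaussian quality noise.
#' @return An object of class `gc_quality_model`.
#' @export
quality_model <- function(base_phred = 37, degrade_above_gc = 65,
                          degrade_slope = 0, noise_sd = 0) {
  structure(list(base_phred = base_phred, degrade_above_gc = degrade_above_gc,
                 degrade_slope = degrade_slope, noise_sd = noise_sd),
            class = "gc_quality_model")
}

#' Simulate GC-biased reads with GC-dependent quality
#'
#' Read sequences are fragments drawn exactly as in [simulate_depth()]; each
#' read's Phred scores come from `quality_model` as a function of its GC
#' content. Identical inputs give byte-identical FASTQ.
#'
#' @param assembly A named `DNAStringSet`.
#' @param bias_model A `gc_bias_model` (default [bias_none()]).
#' @param quality_model A [quality_model()].
#' @param n_reads Number of reads to draw.
#' @param read_length Read length (default 150).
#' @param seed Integer seed.
#' @param path Optional FASTQ output path.
#' @return Invisibly when `path` is given, otherwise visibly: a list with
#'   `sequences` (named `DNAStringSet`) and `qualities` (list of integer
#'   vectors), the shape accepted by [write_fastq()].
#' @export
simulate_fastq <- function(assembly, bias_model = bias_none(), quality_model,
                           n_reads, read_length = 150L, seed, path = NULL) {
  stopifnot(n_reads > 0, inherits(quality_model, "gc_quality_model"))
  reads <- with_seed(seed, {
    frags <- sample_fragments(assembly, bias_model, n_reads, read_length)
    seqs <- character(n_reads)
    for (ctg in unique(frags$contig)) {
      rows <- which(frags$contig == ctg)
      seqs[rows] <- as.character(Biostrings::Views(
        assembly[[ctg]], start = frags$start[rows], width = read_length))
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("read_%07d", seq_len(n_reads))
    counts <- Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T"))
    n_unamb <- pmax(rowSums(counts), 1L)
    gc <- 100 * (counts[, "C"] + counts[, "G"]) / n_unamb
    q <- quality_model$base_phred -
      quality_model$degrade_slope * pmax(0, gc - quality_model$degrade_above_gc) +
      rnorm(n_reads, 0, quality_model$noise_sd)
    q <- as.integer(pmin(41L, pmax(2L, round(q))))
    list(sequences = dss,
         qualities = lapply(q, function(qi) rep(qi, read_length)))
  })
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}
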