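# End-to-end runs wiring the pipeline stages together, with a machine-readable
# manifest so every output directory records exactly how it was produced.

default_params <- function() {
  list(window_width = 500L, stride = NULL, reference_gc_bin = 49L,
       min_bin_windows = 3L, min_contig_length = 10000L, z_threshold = 10,
       exclude_contigs = character(), min_unambiguous_frac = 0.9,
       geometric_mean = FALSE, min_bin_windows_meta = 1L, seed = 1L)
}

resolve_params <- function(...) {
  user <- list(...)
  params <- modifyList(default_params(), user[!vapply(user, is.null, logical(1))])
  if (is.null(params$stride)) params$stride <- params$window_width
  params
}

write_manifest <- function(out_dir, mode, inputs, params, outputs) {
  existing <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest <- list(
    tool = "gcprofile",
    version = as.character(utils::packageVersion("gcprofile")),
    mode = mode,
    inputs = lapply(inputs, function(p) {
      if (is.character(p) && length(p) == 1L && file.exists(p)) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      } else p
    }),
    parameters = params,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, existing))), existing))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the genome-mode GC-bias analysis
#'
#' Reads an assembly and depth (TSV or BAM), filters contigs by length,
#' exclusion list and coverage outlier status, windows the survivors,
#' normalizes to the reference GC bin, summarizes per bin and fits the
#' weighted quadratic bias curve. Writes `windows.tsv`, `profile.tsv`,
#' `fit.json`, `filter_report.tsv`, `bias_profile.pdf` and `manifest.json`
#' into `out_dir`.
#'
#' @param fasta Path to the assembly FASTA.
#' @param depth Path to a 3-column depth TSV, or to an indexed BAM.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param features Optional BED path of feature intervals; when given, the
#'   feature/background coverage ratio over the retained contigs is computed
#'   and written to `feature_ratio.json`.
#' @param window_width,stride,reference_gc_bin,min_bin_windows
#'   Analysis parameters (defaults 500, `window_width`, 49, 3).
#' @param min_contig_length,z_threshold,exclude_contigs Contig-filter
#'   parameters (defaults 10000, 10, none).
#' @param min_unambiguous_frac Minimum A/C/G/T fraction per window.
#' @return A list with `filter`, `windows`, `profile`, `fit` and (if
#'   requested) `feature_ratio`.
#' @export
run_genome_bias <- function(fasta, depth, out_dir = NULL, features = NULL,
                            window_width = NULL, stride = NULL,
                            reference_gc_bin = NULL, min_bin_windows = NULL,
                            min_contig_length = NULL, z_threshold = NULL,
                            exclude_contigs = NULL,
                            min_unambiguous_frac = NULL) {
  params <- resolve_params(window_width = window_width, stride = stride,
                           reference_gc_bin = reference_gc_bin,
                           min_bin_windows = min_bin_windows,
                           min_contig_length = min_contig_length,
                           z_threshold = z_threshold,
                           exclude_contigs = exclude_contigs,
                           min_unambiguous_frac = min_unambiguous_frac)
  assembly <- read_assembly(fasta)
  tracks <- read_depth_any(depth, assembly)
  filt <- filter_contigs(assembly, tracks,
                         min_length = params$min_contig_length,
                         z_threshold = params$z_threshold,
                         exclude = params$exclude_contigs)
  message(length(filt$retained), "/", length(assembly),
          " contigs retained after filtering")
  kept <- assembly[filt$retained]
  wt <- make_windows(kept, tracks[filt$retained],
                     width = params$window_width, stride = params$stride,
                     min_unambiguous_frac = params$min_unambiguous_frac)
  message(nrow(wt), " windows (", attr(wt, "n_invalid_gc"),
          " dropped for ambiguous bases)")
  wt <- normalize_windows(wt, reference_bin = params$reference_gc_bin,
                          min_ref_windows = params$min_bin_windows)
  profile <- bin_profile(wt, min_windows_per_bin = params$min_bin_windows)
  fit <- fit_quadratic(profile)
  res <- list(filter = filt, windows = wt, profile = profile, fit = fit)
  if (!is.null(features)) {
    feats <- read_bed_features(features, assembly)
    keep <- as.character(GenomicRanges::seqnames(feats)) %in% filt$retained
    res$feature_ratio <- feature_background_ratio(tracks[filt$retained],
                                                  feats[keep])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(as.data.frame(wt), file.path(out_dir, "windows.tsv"))
    write_tsv(profile, file.path(out_dir, "profile.tsv"))
    write_fit_json(fit, file.path(out_dir, "fit.json"))
    write_tsv(filt$stats, file.path(out_dir, "filter_report.tsv"))
    mean_gc <- sum(profile$gc_bin * profile$n_windows) / sum(profile$n_windows)
    p <- plot_bias_profile(profile, fit, mean_gc = mean_gc)
    ggplot2::ggsave(file.path(out_dir, "bias_profile.pdf"), p,
                    width = 7, height = 5)
    if (!is.null(res$feature_ratio)) {
      jsonlite::write_json(res$feature_ratio,
                           file.path(out_dir, "feature_ratio.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    write_manifest(out_dir, "genome-bias",
                   list(fasta = fasta, depth = depth, features = features),
                   params,
                   c("windows.tsv", "profile.tsv", "fit.json",
                     "filter_report.tsv", "feature_ratio.json"))
  }
  invisible(res)
}

#' Run the metagenome-mode GC-bias analysis
#'
#' Drops contigs shorter than the length cutoff (no coverage-based filtering:
#' metagenome contigs are independent genetic elements with genuinely
#' different abundances), windows each survivor, averages coverage per GC bin
#' within each contig and builds the cross-contig pairwise coverage-ratio
#' matrix. Writes `ratio_matrix.tsv`, `ratio_heatmap.png` and
#' `manifest.json`.
#'
#' @inheritParams run_genome_bias
#' @param geometric_mean Average ratios geometrically across contigs
#'   (exactly antisymmetric) instead of arithmetically (the default, a
#'   literal cross-contig mean of ratios).
#' @param min_bin_windows_meta Minimum windows per (contig, GC bin) cell.
#' @return A list with `windows`, `bin_means` and `matrix`.
#' @export
run_meta_bias <- function(fasta, depth, out_dir = NULL,
                          window_width = NULL, stride = NULL,
                          min_contig_length = NULL,
                          min_unambiguous_frac = NULL,
                          geometric_mean = NULL, min_bin_windows_meta = NULL) {
  params <- resolve_params(window_width = window_width, stride = stride,
                           min_contig_length = min_contig_length,
                           min_unambiguous_frac = min_unambiguous_frac,
                           geometric_mean = geometric_mean,
                           min_bin_windows_meta = min_bin_windows_meta)
  assembly <- read_assembly(fasta)
  tracks <- read_depth_any(depth, assembly)
  keep <- names(assembly)[Biostrings::width(assembly) >= params$min_contig_length]
  message(length(keep), "/", length(assembly), " contigs at or above ",
          params$min_contig_length, " bp")
  if (length(keep) == 0L) stop("no contig reaches the length cutoff")
  wt <- make_windows(assembly[keep], tracks[keep],
                     width = params$window_width, stride = params$stride,
                     min_unambiguous_frac = params$min_unambiguous_frac)
  bm <- contig_bin_means(wt, min_windows_per_bin = params$min_bin_windows_meta)
  rm_ <- ratio_matrix(bm, geometric = params$geometric_mean)
  res <- list(windows = wt, bin_means = bm, matrix = rm_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_ratio_matrix(rm_, file.path(out_dir, "ratio_matrix.tsv"))
    ggplot2::ggsave(file.path(out_dir, "ratio_heatmap.png"),
                    plot_ratio_heatmap(rm_), width = 7, height = 6)
    write_manifest(out_dir, "meta-bias", list(fasta = fasta, depth = depth),
                   params, "ratio_matrix.tsv")
  }
  invisible(res)
}

#' Run the read-quality versus GC diagnostics
#'
#' Compares a quality-filtered and an unfiltered FASTQ from the same library:
#' per-GC-bin boxplot statistics of per-read median Phred scores (from the
#' unfiltered set) and per-bin proportion ratios quantifying which GC
#' contents quality filtering removes. Writes `quality_by_gc.tsv`,
#' `proportion_ratios.tsv`, both plots, and `manifest.json`.
#'
#' @param filtered_fastq,unfiltered_fastq FASTQ paths.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param bin_width GC bin width in percentage points (default 1).
#' @return A list with `quality_stats` and `ratios`.
#' @export
run_read_qc <- function(filtered_fastq, unfiltered_fastq, out_dir = NULL,
                        bin_width = 1) {
  rq_u <- read_gc_quality(unfiltered_fastq)
  rq_f <- read_gc_quality(filtered_fastq)
  stats <- quality_bin_stats(rq_u)
  ratios <- filter_proportion_ratios(rq_f, rq_u, bin_width = bin_width)
  res <- list(quality_stats = stats, ratios = ratios)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(stats, file.path(out_dir, "quality_by_gc.tsv"))
    write_tsv(ratios, file.path(out_dir, "proportion_ratios.tsv"))
    ggplot2::ggsave(file.path(out_dir, "quality_by_gc.pdf"),
                    plot_quality_by_gc(stats), width = 7, height = 5)
    ggplot2::ggsave(file.path(out_dir, "proportion_ratios.pdf"),
                    plot_filter_ratios(ratios), width = 7, height = 5)
    write_manifest(out_dir, "read-qc",
                   list(filtered = filtered_fastq, unfiltered = unfiltered_fastq),
                   list(bin_width = bin_width),
                   c("quality_by_gc.tsv", "proportion_ratios.tsv"))
  }
  invisible(res)
}

#' Run the simulator from a specification file
#'
#' Reads a YAML/JSON simulation spec and writes an assembly FASTA, a depth
#' TSV, optionally a BAM and a FASTQ, plus `truth.json` recording the
#' injected bias and island intervals for downstream validation.
#'
#' The spec file has keys `contigs` (list of `name`, `segments` with
#' `length`/`gc`, optional `islands` with `start`/`end`/`gc`/`label`),
#' `bias` (`kind`: none/quadratic/table, plus `a`,`b` or `efficiency`),
#' `mean_depth`, `read_length`, optional `n_reads` and `quality`
#' (`base_phred`, `degrade_above_gc`, `degrade_slope`, `noise_sd`),
#' `alignments` (write SAM/BAM), and `seed`.
#'
#' @param spec_path Path to the YAML (or JSON) spec.
#' @param out_dir Output directory.
#' @param seed Overrides the spec's seed when given.
#' @return Invisibly, a list with the simulated objects.
#' @export
run_simulate <- function(spec_path, out_dir, seed = NULL) {
  cfg <- yaml::read_yaml(spec_path)
  if (is.null(seed)) seed <- cfg$seed
  stopifnot(!is.null(seed))
  contigs <- lapply(cfg$contigs, function(ctg) {
    list(name = ctg$name,
         segments = do.call(rbind, lapply(ctg$segments, as.data.frame)),
         islands = if (!is.null(ctg$islands))
           do.call(rbind, lapply(ctg$islands, as.data.frame)))
  })
  spec <- genome_spec(contigs)
  bias <- bias_from_config(cfg$bias)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assembly <- simulate_genome(spec, seed = seed)
  write_assembly(assembly, file.path(out_dir, "assembly.fasta"))
  read_length <- if (!is.null(cfg$read_length)) cfg$read_length else 150L
  sim <- simulate_depth(assembly, bias,
                        mean_depth = cfg$mean_depth,
                        read_length = read_length,
                        seed = seed + 1L,
                        alignments = isTRUE(cfg$alignments))
  write_depth_tsv(sim$depth_tracks, file.path(out_dir, "depth.tsv"))
  if (isTRUE(cfg$alignments)) {
    write_sam(sim, assembly, file.path(out_dir, "alignments.sam"), bam = TRUE)
  }
  reads <- NULL
  if (!is.null(cfg$n_reads)) {
    qm <- do.call(quality_model, if (is.null(cfg$quality)) list() else cfg$quality)
    reads <- simulate_fastq(assembly, bias, qm, n_reads = cfg$n_reads,
                            read_length = read_length, seed = seed + 2L,
                            path = file.path(out_dir, "reads.fastq"))
  }
  isl <- spec_islands(spec)
  truth <- list(seed = seed, bias = unclass(bias),
                mean_depth = cfg$mean_depth, read_length = read_length,
                n_fragments = sim$n_fragments,
                islands = if (length(isl)) data.frame(
                  contig = as.character(GenomicRanges::seqnames(isl)),
                  start = GenomicRanges::start(isl),
                  end = GenomicRanges::end(isl),
                  gc = isl$gc, label = isl$label) else NULL)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate", list(spec = spec_path),
                 list(seed = seed),
                 c("assembly.fasta", "depth.tsv", "reads.fastq", "truth.json"))
  invisible(list(assembly = assembly, sim = sim, reads = reads, spec = spec,
                 bias = bias))
}

bias_from_config <- function(bias_cfg) {
  if (is.null(bias_cfg) || bias_cfg$kind == "none") return(bias_none())
  switch(bias_cfg$kind,
    quadratic = bias_quadratic(bias_cfg$a, bias_cfg$b),
    table = bias_table(unlist(bias_cfg$efficiency)),
    stop("unknown bias kind in spec: ", bias_cfg$kind)
  )
}

read_depth_any <- function(depth, assembly) {
  if (grepl("\\.bam$", depth, ignore.case = TRUE)) {
    depth_from_alignments(depth, assembly)
  } else {
    read_depth_tsv(depth, assembly)
  }
}
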