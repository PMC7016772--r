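---
title: "Profiling GC-dependent coverage bias: models, parameters and design choices"
author: "gcprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling GC-dependent coverage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Library preparation and sequencing chemistry select DNA fragments with an
efficiency that depends on fragment base composition. The observable
consequence is that the mean read depth of a genomic window is a function of
its local GC content. Because all windows of a single bacterial chromosome
are equally abundant in the input DNA (assuming minimal replication-fork
effects), a single isolate genome is a natural calibration standard: any
systematic depth/GC relationship within one chromosome is bias, not biology.

gcprofile summarizes that relationship in three complementary statistics.

**Normalized relative coverage (genome mode).** Windows of width $w$
(default 500 nt) are binned by GC content into 1%-wide bins. Window depths
are divided by the mean depth of the windows in a reference bin (49% GC by
default), giving dimensionless relative coverage with the reference bin at
exactly 1. Per bin $g$ the window count $n_g$, mean $\bar{y}_g$ and sample
standard deviation of normalized coverage are reported, and a quadratic

$$\log_{10}\bar{y}_g = a g^2 + b g + c$$

is fitted by weighted least squares with weights $n_g$. The weighted
$R^2 = 1 - SS_{res}/SS_{tot}$ (both sums weighted, $SS_{tot}$ about the
weighted mean) measures how much of the between-bin coverage variation GC
content explains. A strongly GC-coupled short-read workflow typically gives
a dome ($a<0$) peaking near 50–60% GC with $R^2 > 0.9$.

**Pairwise GC-bin coverage ratios (metagenome mode).** Metagenome contigs
come from organisms of genuinely different abundance, and no single GC bin
is present in all contigs, so cross-contig normalization to one bin is not
possible. Instead, within each contig the mean depth per GC bin is computed,
and for every ordered bin pair $(i, j)$ present in a contig the ratio
$r = \bar{d}_i / \bar{d}_j$ is formed. Ratios are averaged arithmetically
across all contigs containing both bins and the $\log_{10}$ of the average
is stored with the supporting contig count. Within-contig ratios cancel the
contig's abundance, so the matrix isolates the GC effect.

**Read-quality interaction.** Per-read GC content (over unambiguous bases)
against per-read median Phred score, summarized per 1% GC bin by a
median/IQR/10th–90th-percentile boxplot; and the per-bin ratio of GC-
histogram proportions between a quality-filtered and an unfiltered read
set. Ratios below 1 above some GC threshold indicate that quality filtering
itself removes high-GC reads and thereby contributes to the coverage bias.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_width` | 500 | nt | small enough to resolve rRNA-scale GC islands, large enough that binomial GC noise per window (sd $\approx 2.2$ points at 50% GC) does not smear the bins; conclusions are stable from 50 to 5000 nt |
| `stride` | `window_width` | nt | non-overlapping windows make per-bin standard deviations meaningful (independent observations); overlap is available for fine tracks |
| `reference_gc_bin` | 49 | % GC | a bin that bacterial assemblies across a wide range of global GC contents tend to populate; any bin with enough windows works, and the error message lists candidates |
| `min_bin_windows` | 3 | windows | below this a bin mean (and its sd) is too noisy to plot or fit |
| `min_contig_length` | 10000 | bases | removes plasmid-scale elements and small repeat/phage contigs whose copy number is not 1; raise it (e.g. to 100 kb) for assemblies whose mid-size contigs are erratically covered |
| `z_threshold` | 10 | — | modified z-score cutoff on per-contig mean depth; very conservative, catching only clear multi-copy or contaminant contigs |
| `min_unambiguous_frac` | 0.9 | fraction | windows with more than 10% ambiguous bases are excluded rather than letting N-rich windows distort the GC axis |

## Numerical choices

* **GC bins are centered on integers with round-half-up**, so a 49.0%-GC
  window lands in bin 49 — the normalization anchor contains the windows
  closest to its nominal GC. The bin-edge convention is not otherwise
  critical.
* **Per-bin means are arithmetic in linear space, log-transformed
  afterwards** (the log of the average coverage, not the average of logs).
* **Standard deviations use the $n-1$ estimator**; bins reaching the
  profile have $n \ge 3$.
* **Contig outlier scores** use the MAD-based modified z-score with the
  0.6745 consistency constant; when the MAD is zero the mean absolute
  deviation with the 1.253314 constant takes its place, and when that is
  also zero all scores are 0 (a single contig is therefore never removed).
  The filter is applied two-sided: high-coverage outliers are multi-copy
  elements, low-coverage outliers are likely contaminants — both violate
  the equal-abundance assumption that normalization relies on.
* **Arithmetic versus geometric ratio averaging.** Averaging ratios
  arithmetically across contigs and then taking the log is the literal
  "average coverage ratio", but it makes the matrix only approximately
  antisymmetric: by AM–GM, $M_{ij} + M_{ji} \ge 0$, with equality iff the
  pair's ratio is identical in every contributing contig. The package
  surfaces this property (it is asserted in the test suite) and offers
  `geometric = TRUE` for the exactly antisymmetric alternative.
* **Zero-depth bins** are excluded from ratio formation rather than
  producing infinities; zero-mean bins are likewise dropped from profiles
  before the log transform, with a warning.
* **Percentiles** use linear interpolation between order statistics
  (R quantile type 7).
* **Coordinates.** Internally the package uses the native R/Bioconductor
  conventions (1-based vectors, 1-based closed `GRanges`); the 1-based
  depth-TSV dialect and 0-based BED input are converted at the readers, and
  window-table exports carry 0-based half-open `start`/`end` so they match
  the BED ecosystem. Keeping the host language's convention internally,
  with conversions only at format boundaries, is the same single-convention
  discipline that a 0-based core would give.
* **Degenerate inputs.** Contigs shorter than one window yield no windows
  (logged, not fatal); an empty reference bin, fewer than 3 surviving bins,
  a rank-deficient fit design, an all-filtered assembly, and a metagenome
  without any two-bin contig are hard errors with diagnostics.

## The simulator: what it emulates and what it does not

The simulator is the package's ground truth. `simulate_genome()` draws
bases i.i.d. per segment at a target GC (islands overwrite their intervals),
so a spec can emulate, e.g., a 29%-GC chromosome carrying 55%-GC rRNA-like
islands. `simulate_depth()` places
$n = \texttt{mean\_depth} \cdot L / \texttt{read\_length}$ fragments with
probability proportional to $10^{e(g_{frag})}$, where $e$ is the injected
log10 relative efficiency of the fragment's own GC content — selection acts
at the fragment scale, as it does in library preparation, and window-level
analysis then observes the smoothed consequence. Depth noise is the
multinomial placement noise itself (Poisson-like at these depths).
`simulate_fastq()` draws read sequences the same way and assigns each read
a single Phred level from a plateau/threshold/slope/noise quality model,
clipped to [2, 41].

Features of real data deliberately not modeled: platform-specific
substitution/indel error profiles, paired-end insert-size structure,
duplicate reads, mappability artifacts, replication-origin coverage waves,
and any mechanism-level account of *why* a workflow is biased. Passing
tests therefore demonstrate that the statistics measure what they claim to
measure on data with a known injected bias — not that any particular real
workflow follows a quadratic law.

**A known and quantified limitation: fragment-to-window attenuation.**
Because efficiency acts on 150-nt fragments while the analysis bins 500-nt
windows, the observed curve is a smoothed version of the injected one. For
a quadratic log-efficiency with curvature $a$, averaging $10^{e}$ over the
fragment-GC spread around a window's GC (variance
$\sigma^2 \approx p(1-p)/\ell \cdot 10^4$ GC-percentage-points², i.e.
$\sigma^2 \approx 16$ for $\ell = 150$) shrinks the observed curvature by
$1/(1 + 2\ln(10)\,|a|\,\sigma^2) \approx 0.90$ at $a = -0.0015$. The
validation suite measures exactly this: the recovered curvature is
reproducibly $\approx 0.91$ of the injected value with $R^2 > 0.999$ and
the optimum GC recovered within 0.2 points. The practical reading is that
window-scale bias curves slightly understate the fragment-scale selection
strength, by a factor computable from the window and fragment lengths.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` run entirely on simulated data:
a 2 Mb single-chromosome landscape spanning 30–68% GC at 50x for the
flatness null and parameter recovery; a 440 kb 29%-GC chromosome with four
10 kb 55%-GC islands under a tabulated 10-fold efficiency contrast for the
island over-coverage check (the simulated analogue of rRNA-locus coverage
spikes); 50 contigs of 30 kb at 30x for the metagenome flatness null;
1000 randomized per-contig bin-mean fixtures for the ratio-matrix algebra;
and 60 000 reads from a landscape with a small (≈2%) high-GC tail for the
quality-filtering interaction, with base Phred 37 degrading at
6 Phred/GC-point above 65% GC (noise sd 1.5) against a median-Q30 filter.
The high-GC tail is kept small on purpose: removing a fraction $f$ of all
reads inflates every other bin's proportion ratio by $1/(1-f)$, so a large
tail would confound the per-bin signal with renormalization. These sizes
were chosen as the smallest at which the statistics' standard errors are
well below the effects being asserted.

## Using the package on real data

```{r real, eval = FALSE}
library(gcprofile)

# genome mode: assembly + BAM (or samtools-depth-style TSV)
res <- run_genome_bias("assembly.fasta", "alignments.bam", out_dir = "gcbias")
res$fit

# metagenome mode
meta <- run_meta_bias("metagenome.fasta", "alignments.bam", out_dir = "gcbias_meta")
plot_ratio_heatmap(meta$matrix)

# read-quality interaction between two FASTQs from the same library
qc <- run_read_qc("filtered.fastq", "raw.fastq", out_dir = "readqc")
```

Alignments should contain primary alignments of cleaned reads; secondary
and supplementary records are ignored (the 0x900 flag convention) and no
duplicate marking is applied. Known multi-copy elements (plasmids) can be
removed by name with `exclude_contigs`.
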