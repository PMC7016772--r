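Package: gcprofile
Title: Quantify GC-Dependent Coverage Bias in Genome and Metagenome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify guanine-cytosine (GC) dependent coverage bias in
    high-throughput sequencing data. Computes local GC content and mean read
    depth in sliding genomic windows, filters short and aberrantly covered
    contigs with a robust modified z-score, normalizes window coverage to a
    reference GC bin and fits weighted quadratic bias curves (genome mode),
    summarizes within-contig pairwise GC-bin coverage ratios across metagenome
    contigs (metagenome mode), and relates per-read GC content to base quality
    and quality filtering. A bundled simulator generates assemblies, depth
    tracks, alignments and reads with a known injected GC bias so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
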