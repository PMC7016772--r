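#' Read an assembly from FASTA
#'
#' Reads a (multi-)FASTA assembly into a [Biostrings::DNAStringSet].
#' Lowercase bases are uppercased, record order is preserved, and any IUPAC
#' ambiguity code or gap character outside `{A,C,G,T,N}` is replaced by `N`
#' with a warning (draft assemblies routinely contain a handful of them).
#' Contig names are taken as the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet` over the alphabet `{A,C,G,T,N}`.
#' @export
read_assembly <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dups <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate contig name(s) in ", path, ": ", paste(dups, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence record(s) in ", path)
  }
  ambig <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "-", "+", ".")
  n_ambig <- sum(Biostrings::letterFrequency(seqs, letters = paste(ambig, collapse = "")))
  if (n_ambig > 0L) {
    warning(n_ambig, " non-ACGTN base(s) replaced by N in ", path)
    fixed <- gsub("[^ACGTN]", "N", as.character(seqs))
    seqs <- Biostrings::DNAStringSet(setNames(fixed, names(seqs)))
  }
  seqs
}

#' Write an assembly to FASTA
#'
#' @param assembly A named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly, path, width = 70L)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Parses the 3-column TSV dialect emitted by standard depth tools with
#' all-positions output (`contig`, 1-based `position`, integer `depth`).
#' Positions absent from the file are filled with depth 0, and contigs of the
#' assembly entirely absent from the file (possible even in the all-positions
#' dialect when no read aligned to them) yield all-zero tracks, so that every
#' assembly contig maps to a track of exactly its length.
#'
#' @param path Path to the depth TSV (no header).
#' @param assembly A named `DNAStringSet` providing contig names and lengths.
#' @return A named list of integer vectors, one per assembly contig; element
#'   `i` is the read depth at base `i` (1-based).
#' @export
read_depth_tsv <- function(path, assembly) {
  stopifnot(file.exists(path))
  lens <- setNames(Biostrings::width(assembly), names(assembly))
  empty <- file.size(path) == 0L
  if (!empty) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "integer"),
                      col.names = c("contig", "pos", "depth"),
                      quote = "", comment.char = "")
  } else {
    tab <- data.frame(contig = character(), pos = integer(), depth = integer())
  }
  unknown <- setdiff(unique(tab$contig), names(lens))
  if (length(unknown)) {
    stop("depth table refers to contig(s) absent from the assembly: ",
         paste(unknown, collapse = ", "))
  }
  if (any(tab$pos < 1L)) stop("depth table has positions < 1")
  if (any(tab$depth < 0L)) stop("depth table has negative depths")
  tracks <- lapply(names(lens), function(ctg) {
    v <- integer(lens[[ctg]])
    rows <- tab$contig == ctg
    if (any(rows)) {
      p <- tab$pos[rows]
      if (any(p > lens[[ctg]])) {
        stop("depth table position exceeds length of contig ", ctg)
      }
      v[p] <- tab$depth[rows]
    }
    v
  })
  names(tracks) <- names(lens)
  tracks
}

#' Write a per-base depth table
#'
#' Emits the same 3-column, 1-based TSV dialect accepted by
#' [read_depth_tsv()], with all positions present.
#'
#' @param depth_tracks Named list of per-base depth vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth_tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ctg in names(depth_tracks)) {
    v <- depth_tracks[[ctg]]
    write.table(data.frame(ctg, seq_along(v), v), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Per-base depth from a BAM file
#'
#' Computes per-base read depth from a coordinate-sorted, indexed BAM,
#' counting only primary alignments: records with the secondary (0x100) or
#' supplementary (0x800) flag bits set, and unmapped records, are excluded
#' (the `-F 0x900` convention). Reference positions deleted in a read (CIGAR
#' `D`) do not contribute depth, matching the defaults of samtools depth.
#'
#' @param bam_path Path to an indexed BAM file.
#' @param assembly A named `DNAStringSet`; alignment targets must be a subset
#'   of its contigs and lengths must agree with the BAM header.
#' @return A named list of integer vectors as in [read_depth_tsv()].
#' @export
depth_from_alignments <- function(bam_path, assembly) {
  stopifnot(file.exists(bam_path))
  lens <- setNames(Biostrings::width(assembly), names(assembly))
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  unknown <- setdiff(names(hdr), names(lens))
  if (length(unknown)) {
    stop("BAM target(s) absent from the assembly: ", paste(unknown, collapse = ", "))
  }
  mismatch <- names(hdr)[hdr != lens[names(hdr)]]
  if (length(mismatch)) {
    stop("BAM header length disagrees with assembly for: ",
         paste(mismatch, collapse = ", "))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(flag = flag)
  )
  cvg <- GenomicAlignments::coverage(aln, drop.D.ranges = TRUE)
  tracks <- lapply(names(lens), function(ctg) {
    if (ctg %in% names(cvg)) {
      v <- as.integer(cvg[[ctg]])
      length(v) <- lens[[ctg]]          # pads with NA if coverage Rle shorter
      v[is.na(v)] <- 0L
      v
    } else {
      integer(lens[[ctg]])
    }
  })
  names(tracks) <- names(lens)
  tracks
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records with Phred+33 qualities. Malformed records
#' (truncated files, sequence/quality length mismatches) raise an error.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A list with elements `sequences` (a `DNAStringSet`) and
#'   `qualities` (a list of integer Phred vectors, 0--93, parallel to
#'   `sequences`).
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) stop("empty FASTQ file: ", path)
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ record in ", path, " (", n_lines,
         " lines, not a multiple of 4)")
  }
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign notice emitted while the reader rebuilds its container
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  if (any(Biostrings::width(x) != Biostrings::width(Biostrings::quality(x)))) {
    stop("sequence/quality length mismatch in ", path)
  }
  quals <- as(Biostrings::quality(x), "IntegerList")
  S4Vectors::mcols(x) <- NULL
  list(sequences = as(x, "DNAStringSet"), qualities = as.list(quals))
}

#' Write a FASTQ file
#'
#' @param reads A list as returned by [read_fastq()] (`sequences`,
#'   `qualities`), or a `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is(reads, "QualityScaledDNAStringSet")) {
    qs <- reads
  } else {
    stopifnot(length(reads$sequences) == length(reads$qualities))
    qual <- Biostrings::PhredQuality(vapply(
      reads$qualities,
      function(q) rawToChar(as.raw(as.integer(q) + 33L)),
      character(1)
    ))
    qs <- Biostrings::QualityScaledDNAStringSet(reads$sequences, qual)
  }
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read feature intervals from BED
#'
#' Reads 3+1-column BED intervals (0-based half-open on disk) into a
#' 1-based-closed `GRanges` with a `label` metadata column (the BED name
#' field, or `"feature"` when absent). Intervals sharing a label may not
#' overlap.
#'
#' @param path Path to a BED file.
#' @param assembly Optional `DNAStringSet`; when given, intervals are checked
#'   against contig names and lengths.
#' @return A `GRanges` with a `label` column.
#' @export
read_bed_features <- function(path, assembly = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "BED")
  label <- if (!is.null(gr$name)) gr$name else rep("feature", length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(label = label)
  for (lab in unique(label)) {
    sub <- gr[label == lab]
    if (sum(IRanges::width(GenomicRanges::reduce(sub))) <
        sum(IRanges::width(sub))) {
      stop("overlapping intervals within label ", lab, " in ", path)
    }
  }
  if (!is.null(assembly)) {
    lens <- setNames(Biostrings::width(assembly), names(assembly))
    unknown <- setdiff(as.character(GenomicRanges::seqnames(gr)), names(lens))
    if (length(unknown)) {
      stop("BED contig(s) absent from the assembly: ", paste(unknown, collapse = ", "))
    }
    over <- GenomicRanges::end(gr) > lens[as.character(GenomicRanges::seqnames(gr))]
    if (any(over)) stop("BED interval(s) extend beyond contig end in ", path)
  }
  gr
}
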