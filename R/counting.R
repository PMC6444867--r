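#' Per-bin read counting and GC content
#'
#' Converts filtered alignments into raw per-bin counts (one count per
#' retained primary alignment, assigned by leftmost aligned base) and
#' computes per-bin GC fractions from a reference FASTA.
#'
#' @name counting
NULL

#' Construct a per-bin counts vector
#'
#' Internal container for staged counts aligned to a \code{bin_set}.
#' Stages: \code{raw} (integer counts), \code{gc_corrected} (fractional),
#' \code{normalized_percent} (sums to 100 over usable bins).
#'
#' @param counts Numeric vector, one entry per bin (NA allowed for masked
#'   bins after correction).
#' @param bins The \code{bin_set} the counts align to.
#' @param sample_id Sample label.
#' @param stage One of \code{"raw"}, \code{"gc_corrected"},
#'   \code{"normalized_percent"}.
#' @return A \code{bin_counts} object.
#' @export
bin_counts <- function(counts, bins, sample_id = "sample", stage = "raw") {
  stopifnot(inherits(bins, "bin_set"))
  stage <- match.arg(stage, c("raw", "gc_corrected", "normalized_percent"))
  if (length(counts) != nrow(bins))
    stop("counts length (", length(counts), ") != number of bins (",
         nrow(bins), ")")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (stage == "normalized_percent") {
    tot <- sum(counts[bins$usable], na.rm = TRUE)
    if (abs(tot - 100) > 1e-9)
      stop("normalized_percent counts must sum to 100 over usable bins (got ",
           format(tot), ")")
  }
  structure(list(sample_id = sample_id, counts = as.numeric(counts),
                 stage = stage,
                 total = sum(counts[bins$usable], na.rm = TRUE)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s' [%s]: %d bins, usable total %.4g\n",
              x$sample_id, x$stage, length(x$counts), x$total))
  invisible(x)
}

#' Count retained reads per bin
#'
#' Counts each retained alignment once, in the bin containing its leftmost
#' aligned base (bins are half-open, so a read starting at the first base
#' of a bin belongs to that bin).  A read is retained iff it is mapped,
#' primary (not secondary, not supplementary), not flagged as a duplicate,
#' and has MAPQ >= \code{mapq_min}.  Reads on contigs absent from the bin
#' set are skipped and tallied in the \code{skipped_off_contig} attribute.
#'
#' @param alignments Path to a BAM file, or a SAM text file (converted on
#'   the fly).
#' @param bins A \code{bin_set}.
#' @param mapq_min Minimum mapping quality (default 60; with BWA-MEM this
#'   keeps uniquely mapped reads).
#' @param sample_id Sample label (default: file name).
#' @return A \code{bin_counts} object at stage \code{"raw"}, with attribute
#'   \code{skipped_off_contig}.
#' @export
count_reads <- function(alignments, bins, mapq_min = 60,
                        sample_id = sub("\\.(bam|sam)$", "", basename(alignments))) {
  stopifnot(inherits(bins, "bin_set"), nrow(bins) > 0L)
  if (!file.exists(alignments)) stop("alignment file not found: ", alignments)
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$mapq) & rec$mapq >= mapq_min & !is.na(rec$pos)
  chrom <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L  # leftmost aligned base, 0-based

  on_contig <- chrom %in% unique(bins$chrom)
  skipped <- sum(!on_contig)
  chrom <- chrom[on_contig]
  pos0 <- pos0[on_contig]

  counts <- integer(nrow(bins))
  if (length(pos0) > 0L) {
    bs <- attr(bins, "bin_size")
    # map (chrom, within-chrom bin ordinal) -> global row
    key_reads <- paste(chrom, pos0 %/% bs)
    key_bins <- paste(bins$chrom, bins$start %/% bs)
    idx <- match(key_reads, key_bins)
    ok <- !is.na(idx)
    skipped <- skipped + sum(!ok)
    tab <- tabulate(idx[ok], nbins = nrow(bins))
    counts <- tab
  }
  out <- bin_counts(counts, bins, sample_id = sample_id, stage = "raw")
  attr(out, "skipped_off_contig") <- skipped
  out
}

#' Per-bin GC fraction from a reference FASTA
#'
#' GC is computed over unambiguous bases only: gc = (G+C)/(A+C+G+T).
#' Bins consisting entirely of N get \code{NA} gc; downstream fitting
#' treats them as unusable.
#'
#' @param reference Path to an (indexed or indexable) FASTA containing all
#'   bin-set chromosomes.
#' @param bins A \code{bin_set}.
#' @return A \code{gc_track}: data frame with columns \code{gc} and
#'   \code{n_fraction}, one row per bin.
#' @export
compute_gc <- function(reference, bins) {
  stopifnot(inherits(bins, "bin_set"))
  fa <- Rsamtools::FaFile(reference)
  if (!file.exists(paste0(reference, ".fai")))
    Rsamtools::indexFa(reference)
  seqinfo_names <- as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(fa)))
  missing <- setdiff(unique(bins$chrom), seqinfo_names)
  if (length(missing) > 0L)
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))
  gr <- .bins_granges(bins)
  seqs <- Rsamtools::scanFa(fa, param = gr)
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T", "N"))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  width <- BiocGenerics::width(seqs)
  gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
  out <- data.frame(gc = gc, n_fraction = freq[, "N"] / width)
  class(out) <- c("gc_track", "data.frame")
  out
}

#' Write / read staged counts as TSV
#'
#' One row per bin: chrom, start, end, index, count; a header comment
#' records the sample id and stage, so the pipeline can resume from a
#' counts table without any alignment file.
#'
#' @param counts A \code{bin_counts}.
#' @param bins The matching \code{bin_set}.
#' @param path File path.
#' @return \code{read_counts_tsv} returns a \code{bin_counts}.
#' @export
write_counts_tsv <- function(counts, bins, path) {
  stopifnot(inherits(counts, "bin_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s stage=%s", counts$sample_id,
                     counts$stage), con)
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   index = bins$index, count = counts$counts)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, bins) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("sample_id=(\\S+) stage=(\\S+)", first))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) != nrow(bins) || any(df$index != bins$index))
    stop("counts table does not match bin set: ", path)
  bin_counts(df$count, bins,
             sample_id = if (length(m) == 3L) m[2] else "sample",
             stage = if (length(m) == 3L) m[3] else "raw")
}
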