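#' Genome builds and fixed-size bin grids
#'
#' The instability pipeline operates on an ordered grid of fixed-size bins
#' tiling the autosomes.  A genome build is a data frame of chromosome names
#' and lengths; \code{make_bins()} tiles it and \code{apply_blacklist()}
#' masks bins overlapping excluded regions (centromeres, telomeres, low
#' mappability).
#'
#' @name genome
NULL

# UCSC hg19 autosome lengths (chr1-chr22).
.HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566
)

# hg19 centromere gap intervals (0-based, half-open), UCSC gap track.
.HG19_CENTROMERES <- data.frame(
  chrom = names(.HG19_LENGTHS),
  start = c(121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
            58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
            16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
            24681782, 26369569, 11288129, 13000000),
  end = c(124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
          61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
          19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
          27681782, 29369569, 14288129, 16000000),
  stringsAsFactors = FALSE
)

#' hg19 autosome genome build
#'
#' Chromosome names and lengths for the 22 human autosomes (UCSC hg19).
#' Sex chromosomes are excluded by design: instability scoring is defined
#' over the autosomal genome only.
#'
#' @return A \code{genome_build}: data frame with columns \code{chrom} and
#'   \code{length}, attribute \code{name = "hg19"}.
#' @export
#' @examples
#' b <- hg19_build()
#' sum(ceiling(b$length / 1e6))  # 2897 one-megabase bins
hg19_build <- function() {
  genome_build(data.frame(chrom = names(.HG19_LENGTHS),
                          length = unname(.HG19_LENGTHS),
                          stringsAsFactors = FALSE),
               name = "hg19")
}

#' hg19 centromere gap intervals
#'
#' 0-based half-open centromere gap coordinates for the hg19 autosomes,
#' used by \code{\link{hg19_example_blacklist}} and to define chromosome
#' arms in the synthetic-cohort generator.
#'
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
hg19_centromeres <- function() .HG19_CENTROMERES

#' Construct a genome build
#'
#' @param chromosomes Data frame with columns \code{chrom} (unique names)
#'   and \code{length} (positive bp).
#' @param name Text label for the build.
#' @return A \code{genome_build} object (data frame).
#' @export
genome_build <- function(chromosomes, name = "custom") {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L)
    stop("genome build has no chromosomes")
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicate chromosome names in genome build")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be strictly positive")
  out <- data.frame(chrom = as.character(chromosomes$chrom),
                    length = as.numeric(chromosomes$length),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Read a chrom.sizes-style TSV as a genome build
#'
#' Two columns, no header: chromosome name and length in bp.
#'
#' @param path Path to the TSV.
#' @param name Build label.
#' @return A \code{genome_build}.
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_build(df, name = name)
}

#' Tile a genome build into fixed-size bins
#'
#' Divides every chromosome into consecutive bins of \code{bin_size} bp
#' (0-based, half-open).  The final bin of each chromosome is kept even when
#' shorter than \code{bin_size}, so each chromosome contributes
#' \code{ceiling(length / bin_size)} bins.  For hg19 autosomes at 1 Mb this
#' gives 2897 bins.  All bins start out usable.
#'
#' @param build A \code{genome_build}.
#' @param bin_size Bin width in bp (default 1e6).
#' @return A \code{bin_set}: data frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{index} (0-based ordinal over the
#'   genome), \code{usable}; attributes \code{bin_size} and \code{build}.
#' @export
#' @examples
#' bins <- make_bins(hg19_build())
#' nrow(bins)  # 2897
make_bins <- function(build, bin_size = 1e6) {
  if (!inherits(build, "genome_build"))
    build <- genome_build(build)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  pieces <- lapply(seq_len(nrow(build)), function(i) {
    len <- build$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = build$chrom[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  bins$usable <- TRUE
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size
  attr(bins, "build") <- attr(build, "name")
  class(bins) <- c("bin_set", "data.frame")
  bins
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins of %s bp on %d chromosome(s) [%s], %d usable\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom)),
              attr(x, "build") %||% "?", sum(x$usable)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bin_set -> GRanges (internal); bins are 0-based half-open.
.bins_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1, end = bins$end))
}

#' Mask bins overlapping blacklist regions
#'
#' A bin's \code{usable} flag is set \code{FALSE} iff it overlaps any
#' blacklist interval by at least 1 bp; other flags are untouched, so the
#' operation is idempotent and composes over multiple blacklists.  Intervals
#' on chromosomes absent from the bin set are skipped with a warning.
#'
#' @param bins A \code{bin_set}.
#' @param regions Blacklist intervals: a data frame with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based, half-open, BED
#'   convention) or a path to a BED3 file.
#' @return A new \code{bin_set} with updated \code{usable} flags.
#' @export
apply_blacklist <- function(bins, regions) {
  stopifnot(inherits(bins, "bin_set"))
  if (is.character(regions) && length(regions) == 1L)
    regions <- read_bed3(regions)
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) == 0L) return(bins)
  unknown <- !(regions$chrom %in% unique(bins$chrom))
  if (any(unknown)) {
    warning(sprintf("skipping %d blacklist interval(s) on chromosome(s) not in bin set: %s",
                    sum(unknown),
                    paste(unique(regions$chrom[unknown]), collapse = ", ")))
    regions <- regions[!unknown, , drop = FALSE]
    if (nrow(regions) == 0L) return(bins)
  }
  gr_bins <- .bins_granges(bins)
  gr_bl <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(start = regions$start + 1,
                                                   end = regions$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_bl, minoverlap = 1L)
  bins$usable[unique(S4Vectors::queryHits(hits))] <- FALSE
  bins
}

#' Read a BED3 file
#'
#' @param path Path to a 3+ column BED file (0-based, half-open).
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns: ", path)
  data.frame(chrom = as.character(df[[1]]),
             start = as.numeric(df[[2]]),
             end = as.numeric(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED3
#'
#' @param regions Data frame with \code{chrom}, \code{start}, \code{end}.
#' @param path Output path.
#' @export
write_bed3 <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a bin set as TSV
#'
#' Columns: chrom, start, end, index, usable.  Coordinates round-trip
#' exactly.
#'
#' @param bins A \code{bin_set}.
#' @param path File path.
#' @return \code{read_bins} returns a \code{bin_set}.
#' @export
write_bins <- function(bins, path) {
  hdr <- sprintf("# bin_size=%.0f build=%s", attr(bins, "bin_size"),
                 attr(bins, "build") %||% "custom")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(bins), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec("bin_size=([0-9.eE+]+) build=(\\S+)", first))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$index <- as.integer(df$index)
  df$usable <- as.logical(df$usable)
  attr(df, "bin_size") <- if (length(meta) == 3L) as.numeric(meta[2]) else NA_real_
  attr(df, "build") <- if (length(meta) == 3L) meta[3] else "custom"
  class(df) <- c("bin_set", "data.frame")
  df
}

#' Example hg19 blacklist covering 163 bins
#'
#' A deterministic, synthetic exclusion list for the hg19 1 Mb grid built
#' from the regions the field routinely masks: the first and last bin of
#' every autosome (telomeric) and the centromere gaps, padded one bin at a
#' time in chromosome order until exactly 163 distinct bins are covered.
#' It illustrates the bookkeeping of a 2897-bin grid with 163 masked and
#' 2734 usable bins; it is not a published mappability track, and any real
#' analysis should supply its own BED.
#'
#' @return Data frame of 0-based half-open intervals (\code{chrom},
#'   \code{start}, \code{end}).
#' @export
#' @examples
#' bins <- apply_blacklist(make_bins(hg19_build()), hg19_example_blacklist())
#' sum(!bins$usable)  # 163
hg19_example_blacklist <- function() {
  build <- hg19_build()
  cen <- hg19_centromeres()
  bs <- 1e6
  base <- rbind(
    data.frame(chrom = build$chrom, start = 0, end = bs),
    data.frame(chrom = build$chrom, start = build$length - 1,
               end = build$length),
    cen
  )
  bins <- make_bins(build, bs)
  n_covered <- function(regs) sum(!apply_blacklist(bins, regs)$usable)
  covered <- n_covered(base)
  if (covered > 163L)
    stop("base blacklist already exceeds 163 bins")  # hg19/1 Mb invariant
  extra <- list()
  # pad rightward from each centromere, round-robin over chromosomes,
  # one whole bin per step, until exactly 163 bins are masked
  pad <- stats::setNames(rep(0L, nrow(cen)), cen$chrom)
  i <- 0L
  while (covered + length(extra) < 163L) {
    chrom <- cen$chrom[(i %% nrow(cen)) + 1L]
    i <- i + 1L
    first_free <- (cen$end[cen$chrom == chrom] %/% bs) + 1L + pad[chrom]
    pad[chrom] <- pad[chrom] + 1L
    extra[[length(extra) + 1L]] <-
      data.frame(chrom = chrom, start = first_free * bs,
                 end = first_free * bs + 1)
  }
  bl <- rbind(base, do.call(rbind, extra))
  rownames(bl) <- NULL
  bl
}
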