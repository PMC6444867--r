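# shared fixture builders; everything is generated in code

# a single-chromosome bin set
tiny_bins <- function(n_bins = 4L, bin_size = 1e6, chrom = "chrT") {
  make_bins(genome_build(data.frame(chrom = chrom,
                                    length = n_bins * bin_size)),
            bin_size = bin_size)
}

# normalized-percent control whose first bin has percentage `p1`,
# remaining usable bins sharing the rest equally
control_with_bin1 <- function(p1, bins, id = "ctl") {
  n <- nrow(bins)
  vals <- c(p1, rep((100 - p1) / (n - 1), n - 1))
  bin_counts(vals, bins, sample_id = id, stage = "normalized_percent")
}

# GC-correct + percentage-normalize one raw sample
normalize_sample <- function(cnt, gc, bins, span = 0.3) {
  model <- fit_gc_model(cnt, gc, bins, span = span)
  normalize_percent(correct_counts(cnt, model, bins), bins)
}

# brute-force per-bin overlap check used as the blacklist oracle
overlaps_any <- function(bins, regions) {
  vapply(seq_len(nrow(bins)), function(i) {
    any(regions$chrom == bins$chrom[i] &
          regions$start < bins$end[i] &
          regions$end > bins$start[i])
  }, logical(1))
}
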