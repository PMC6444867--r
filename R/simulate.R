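#' Synthetic cohort generator with known ground truth
#'
#' Generates every input the pipeline consumes: a healthy reference panel
#' of noisy bin counts sharing a smooth GC bias, patient samples carrying
#' arm-level copy-number alterations diluted by a tumor-fraction parameter,
#' tiny SAM fixtures for the read counter, duplex droplet counts for the
#' ddPCR module, and proportional-hazards survival times.  All generators
#' are deterministic functions of (config, seed).
#'
#' The count model: the expected count of bin i is proportional to
#' bin_width * bias(gc_i) * (1 + tf * (copy_state_i - 2) / 2), the standard
#' diploid-admixture model for circulating tumor DNA, and counts are drawn
#' negative-binomial so the panel's bin-to-bin variability is realistic
#' (Poisson would understate healthy-panel SDs).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study: a reference panel of 14 healthy
#' controls; arm-level gains of 1q and 8q and losses of 1p, 4q and 8p in
#' patients; ~20,000 droplets per ddPCR well; survival times whose hazard
#' is multiplied by a configurable ratio (default 3.5) in the high-risk
#' group.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param genome A \code{genome_build}; default a toy genome of
#'   \code{toy_chroms} chromosomes x \code{toy_mb} Mb, sized so the full
#'   pipeline runs in seconds.
#' @param bin_size Bin width (default 1e6).
#' @param n_controls Healthy panel size (default 14).
#' @param n_patients Number of patient samples (default 20).
#' @param reads_per_sample Expected total read count per sample (default
#'   900 per bin, so per-bin counts are in the hundreds).
#' @param gc_bias Polynomial coefficients (intercept first) of the
#'   multiplicative depth bias as a function of GC in [0,1]; the default
#'   quadratic peaks near GC 0.45 and spans roughly a 1.4x depth range over
#'   the simulated GC values.
#' @param dispersion Negative-binomial overdispersion (variance = mu +
#'   dispersion * mu^2); default 0.002, giving healthy-panel bin
#'   coefficients of variation of a few percent, the scale seen in
#'   GC-corrected 1 Mb cfDNA bins.
#' @param cna_segments Data frame (chrom, start, end, copy_state) of
#'   alterations carried by patients; copy states 0/1 (loss) or 3/4
#'   (gain).  Default: arm-level +1q, +8q, -1p, -4q, -8p on hg19, or a
#'   proportional toy analogue on toy genomes.
#' @param tumor_fraction Per-patient tumor fractions in [0,1); recycled to
#'   \code{n_patients}.  Default 0.2.
#' @param n_droplets Accepted droplets per ddPCR channel (default 20000).
#' @param reference_lambda Mean reference-locus copies per droplet
#'   (default 0.15, a typical loaded well).
#' @param true_copy_number Per-patient true target copy number for the
#'   droplet generator (default 2).
#' @param baseline_median_months Median event time of the low-risk group
#'   (default 14.8 months).
#' @param group_hr Hazard ratio of the high-risk group (default 3.5).
#' @param censoring_rate Probability a subject is censored before the
#'   event (default 0.2).
#' @param toy_chroms,toy_mb Toy genome dimensions (default 3 chromosomes x
#'   40 Mb).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       genome = NULL,
                       bin_size = 1e6,
                       n_controls = 14L,
                       n_patients = 20L,
                       reads_per_sample = NULL,
                       gc_bias = c(-1.2, 9.0, -10.0),
                       dispersion = 0.002,
                       cna_segments = NULL,
                       tumor_fraction = 0.2,
                       n_droplets = 20000L,
                       reference_lambda = 0.15,
                       true_copy_number = 2,
                       baseline_median_months = 14.8,
                       group_hr = 3.5,
                       censoring_rate = 0.2,
                       toy_chroms = 3L, toy_mb = 40L) {
  if (is.null(genome)) genome <- toy_build(toy_chroms, toy_mb)
  bins <- make_bins(genome, bin_size)
  if (is.null(reads_per_sample)) reads_per_sample <- 900 * nrow(bins)
  if (is.null(cna_segments)) cna_segments <- default_cna_segments(genome)
  stopifnot(n_controls >= 2L, n_patients >= 0L, dispersion >= 0,
            all(tumor_fraction >= 0 & tumor_fraction < 1),
            censoring_rate >= 0, censoring_rate < 1,
            n_droplets > 0, reference_lambda >= 0)
  if (nrow(cna_segments) > 0 && any(cna_segments$copy_state == 2))
    stop("cna_segments must list altered states only (copy_state != 2)")
  structure(list(seed = as.integer(seed), genome = genome, bins = bins,
                 bin_size = bin_size, n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 reads_per_sample = reads_per_sample, gc_bias = gc_bias,
                 dispersion = dispersion, cna_segments = cna_segments,
                 tumor_fraction = rep_len(tumor_fraction, max(n_patients, 1L)),
                 n_droplets = as.integer(n_droplets),
                 reference_lambda = reference_lambda,
                 true_copy_number = true_copy_number,
                 baseline_median_months = baseline_median_months,
                 group_hr = group_hr, censoring_rate = censoring_rate),
            class = "sim_config")
}

#' Toy genome build
#'
#' \code{k} chromosomes named chrA, chrB, ... of \code{mb} megabases each.
#'
#' @param k Number of chromosomes.
#' @param mb Chromosome length in Mb.
#' @return A \code{genome_build}.
#' @export
toy_build <- function(k = 3L, mb = 40L) {
  genome_build(data.frame(chrom = paste0("chr", LETTERS[seq_len(k)]),
                          length = rep(mb * 1e6, k)),
               name = sprintf("toy%dx%dMb", k, mb))
}

#' Default copy-number alteration scenario
#'
#' On hg19: whole-arm gain of 1q and 8q (3 copies) and loss of 1p, 4q and
#' 8p (1 copy), the alterations most frequently seen in hepatocellular
#' carcinoma cfDNA.  On other builds: a proportional analogue — gain of
#' the second half of the first chromosome, loss of the first half of the
#' last.
#'
#' @param genome A \code{genome_build}.
#' @return Data frame (chrom, start, end, copy_state).
#' @export
default_cna_segments <- function(genome) {
  if (identical(attr(genome, "name"), "hg19")) {
    cen <- hg19_centromeres()
    cen_mid <- stats::setNames((cen$start + cen$end) / 2, cen$chrom)
    len <- stats::setNames(genome$length, genome$chrom)
    return(data.frame(
      chrom = c("chr1", "chr8", "chr1", "chr4", "chr8"),
      start = c(cen_mid["chr1"], cen_mid["chr8"], 0, cen_mid["chr4"], 0),
      end = c(len["chr1"], len["chr8"], cen_mid["chr1"], len["chr4"],
              cen_mid["chr8"]),
      copy_state = c(3, 3, 1, 1, 1), row.names = NULL))
  }
  first <- genome$chrom[1]
  last <- genome$chrom[nrow(genome)]
  data.frame(chrom = c(first, last),
             start = c(genome$length[1] / 2, 0),
             end = c(genome$length[1], genome$length[nrow(genome)] / 2),
             copy_state = c(3, 1))
}

# per-bin copy state implied by the segment list (majority-overlap by bp)
.bin_copy_state <- function(bins, segments) {
  cs <- rep(2, nrow(bins))
  if (nrow(segments) == 0L) return(cs)
  gr_bins <- .bins_granges(bins)
  gr_seg <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start + 1,
                                                    segments$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_seg)
  if (length(hits) == 0L) return(cs)
  ov <- BiocGenerics::width(IRanges::pintersect(
    gr_bins[S4Vectors::queryHits(hits)], gr_seg[S4Vectors::subjectHits(hits)]))
  binw <- bins$end - bins$start
  keep <- ov >= binw[S4Vectors::queryHits(hits)] / 2
  cs[S4Vectors::queryHits(hits)[keep]] <-
    segments$copy_state[S4Vectors::subjectHits(hits)[keep]]
  cs
}

# deterministic GC track over bins, kept inside [0.35, 0.55] where the
# default bias polynomial is positive.  Spatially irregular on purpose
# (golden-angle sequence): real bin GC varies bin to bin, so a chromosome
# arm spans the whole GC range and arm-level copy-number signal cannot be
# confounded with (and absorbed by) the GC fit.
.simulate_gc <- function(bins) {
  i <- seq_len(nrow(bins))
  0.45 + 0.07 * sin(2.39996323 * i) + 0.03 * sin(i / 13)
}

.polyval <- function(coefs, x) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- out * x + coefs[j]
  out
}

#' Simulate per-bin counts for controls and patients
#'
#' Expected counts follow bin_width * bias(gc) * (1 + tf * (state - 2)/2),
#' rescaled so each sample's expected total equals
#' \code{reads_per_sample}; counts are negative-binomial with the
#' configured dispersion.  Controls carry no alteration (tf = 0).
#'
#' @param config A \code{sim_config}.
#' @return List with \code{controls} and \code{patients} (lists of raw
#'   \code{bin_counts}), \code{gc} (a \code{gc_track}), \code{bins}, and
#'   \code{truth} (per-patient tumor fraction, per-bin copy states,
#'   expected counts).
#' @export
simulate_bin_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- config$bins
  set.seed(config$seed)
  gcv <- .simulate_gc(bins)
  gc <- data.frame(gc = gcv, n_fraction = 0)
  class(gc) <- c("gc_track", "data.frame")
  bias <- .polyval(config$gc_bias, gcv)
  if (any(bias <= 0))
    stop("gc_bias polynomial non-positive over simulated GC range")
  binw <- (bins$end - bins$start) / config$bin_size
  states <- .bin_copy_state(bins, config$cna_segments)
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf

  draw <- function(tf, id) {
    mu <- binw * bias * (1 + tf * (states - 2) / 2)
    mu <- mu * config$reads_per_sample / sum(mu)
    if (any(mu <= 0)) stop("non-positive expected count; tumor fraction ",
                           "and copy states incompatible")
    cnt <- if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
           else stats::rpois(length(mu), mu)
    out <- bin_counts(cnt, bins, sample_id = id, stage = "raw")
    attr(out, "expected") <- mu
    out
  }

  controls <- lapply(seq_len(config$n_controls), function(i)
    draw(0, sprintf("control_%02d", i)))
  patients <- if (config$n_patients > 0)
    lapply(seq_len(config$n_patients), function(i)
      draw(config$tumor_fraction[i], sprintf("patient_%02d", i)))
  else list()

  list(controls = controls, patients = patients, gc = gc, bins = bins,
       truth = list(tumor_fraction = config$tumor_fraction[
                      seq_len(config$n_patients)],
                    copy_state = states,
                    gc_bias = bias,
                    segments = config$cna_segments))
}

#' Emit a SAM fixture realizing a raw counts vector
#'
#' Writes exactly \code{counts} primary MAPQ-60 single-end reads whose
#' leftmost base falls inside each bin, plus optional decoy reads (low
#' MAPQ, duplicate-flagged) that the counter must reject.  Intended for
#' toy genomes only.
#'
#' @param counts A \code{bin_counts} at stage \code{"raw"}.
#' @param bins The matching \code{bin_set}.
#' @param path Output SAM path.
#' @param read_length Read length in bp (default 75).
#' @param n_decoys Number of decoy reads (half low-MAPQ, half
#'   duplicate-flagged; default 0).
#' @param seed Seed for read placement within bins.
#' @return \code{path}, invisibly.
#' @export
simulate_sam <- function(counts, bins, path, read_length = 75L,
                         n_decoys = 0L, seed = 1L) {
  stopifnot(inherits(counts, "bin_counts"), inherits(bins, "bin_set"))
  set.seed(seed)
  chroms <- unique(bins$chrom)
  lens <- vapply(chroms, function(cc) max(bins$end[bins$chrom == cc]), 0)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(lens)))
  seq_str <- strrep("A", read_length)
  qual_str <- strrep("I", read_length)
  recs <- character(0)
  q <- 0L
  for (i in seq_len(nrow(bins))) {
    k <- counts$counts[i]
    if (is.na(k) || k == 0) next
    width <- bins$end[i] - bins$start[i]
    if (width < read_length && k > 0)
      stop("bin ", i, " narrower than the read length")
    # leftmost base uniform inside the bin, read kept inside the chromosome
    maxpos <- min(bins$end[i], max(bins$end[bins$chrom == bins$chrom[i]])) -
      read_length
    pos <- bins$start[i] + sample.int(max(1L, min(width, maxpos - bins$start[i] + 1L)),
                                      k, replace = TRUE) - 1L
    recs <- c(recs, sprintf("read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                            q + seq_len(k), bins$chrom[i], as.integer(pos + 1L),
                            read_length, seq_str, qual_str))
    q <- q + k
  }
  if (n_decoys > 0L) {
    flags <- rep(c(0L, 1024L), length.out = n_decoys)  # plain / duplicate
    mapqs <- ifelse(flags == 0L, 10L, 60L)             # low MAPQ / dup flag
    dchrom <- sample(chroms, n_decoys, replace = TRUE)
    dpos <- vapply(dchrom, function(cc)
      sample.int(as.integer(lens[cc]) - read_length, 1L), 1L)
    recs <- c(recs, sprintf("decoy%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                            seq_len(n_decoys), flags, dchrom, dpos,
                            mapqs, read_length, seq_str, qual_str))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Simulate duplex droplet counts
#'
#' Copies per droplet are Poisson; a droplet is positive iff it holds at
#' least one copy, so positives are binomial with success probability
#' 1 - exp(-lambda).  The target-channel rate is
#' reference_lambda * true_copy_number / 2.
#'
#' @param n_droplets Accepted droplets per channel.
#' @param true_copy_number True target copies per diploid genome.
#' @param reference_lambda Reference-locus copies per droplet.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A \code{droplet_counts}.
#' @export
simulate_droplets <- function(n_droplets = 20000L, true_copy_number = 2,
                              reference_lambda = 0.15, seed = 1L,
                              sample_id = "sim") {
  stopifnot(n_droplets > 0, true_copy_number >= 0, reference_lambda >= 0)
  set.seed(seed)
  lt <- reference_lambda * true_copy_number / 2
  k_t <- stats::rbinom(1L, n_droplets, 1 - exp(-lt))
  k_r <- stats::rbinom(1L, n_droplets, 1 - exp(-reference_lambda))
  droplet_counts(sample_id, k_t, n_droplets, k_r, n_droplets)
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with the low-group hazard set by
#' \code{baseline_median_months}; the high group's hazard is multiplied by
#' \code{group_hr}.  Each subject has an independent exponential censoring
#' time whose rate is chosen so the probability of being censored before
#' the event equals \code{censoring_rate} exactly.  When
#' \code{frailty_sd > 0}, a shared per-subject lognormal frailty multiplies
#' the hazards of both generated endpoints, inducing the TTP/OS
#' correlation seen in real cohorts.
#'
#' @param groups Factor/character with levels \code{low}/\code{high} (or
#'   any two levels; the second is the high-hazard group).
#' @param baseline_median_months Low-group median event time.
#' @param group_hr Hazard ratio for the high group.
#' @param censoring_rate Probability of censoring before the event in
#'   [0, 1).
#' @param n_endpoints How many correlated endpoints to generate (default 2:
#'   TTP and OS).
#' @param frailty_sd SD of the shared log-normal frailty (default 0.5).
#' @param seed Integer seed.
#' @return Data frame with columns \code{group} and, per endpoint k,
#'   \code{time_k} and \code{event_k} (TTP first, OS second when
#'   \code{n_endpoints = 2}).
#' @export
simulate_survival <- function(groups, baseline_median_months = 14.8,
                              group_hr = 3.5, censoring_rate = 0.2,
                              n_endpoints = 2L, frailty_sd = 0.5,
                              seed = 1L) {
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  groups <- as.factor(groups)
  if (nlevels(groups) > 2L) stop("at most 2 groups supported")
  set.seed(seed)
  n <- length(groups)
  base_rate <- log(2) / baseline_median_months
  hr_vec <- ifelse(as.integer(groups) == nlevels(groups), group_hr, 1)
  frailty <- if (frailty_sd > 0)
    exp(stats::rnorm(n, -frailty_sd^2 / 2, frailty_sd)) else rep(1, n)
  out <- data.frame(group = groups)
  for (k in seq_len(n_endpoints)) {
    rate <- base_rate * hr_vec * frailty
    t_event <- stats::rexp(n, rate)
    if (censoring_rate > 0) {
      c_rate <- rate * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n, c_rate)
    } else t_cens <- rep(Inf, n)
    out[[paste0("time_", k)]] <- pmin(t_event, t_cens)
    out[[paste0("event_", k)]] <- as.integer(t_event <= t_cens)
  }
  names(out) <- sub("^time_1$", "ttp_time", names(out))
  names(out) <- sub("^event_1$", "ttp_event", names(out))
  if (n_endpoints >= 2L) {
    names(out) <- sub("^time_2$", "os_time", names(out))
    names(out) <- sub("^event_2$", "os_event", names(out))
  }
  out
}

#' Mean I-score across tumor fractions with common random numbers
#'
#' For comparing instability scores across a ladder of tumor fractions,
#' each replicate reuses one uniform stream across all fractions and draws
#' counts by the negative-binomial quantile function (common random
#' numbers).  Because the quantile function is monotone in its mean, the
#' same replicate scored at a higher tumor fraction deviates at least as
#' far in every altered bin, so the paired design isolates the
#' tumor-fraction effect from between-replicate noise — the standard
#' variance-reduction device for ordered Monte Carlo comparisons.
#'
#' @param config A \code{sim_config}; its controls define the panel.
#' @param tumor_fractions Ladder of tumor fractions (default
#'   c(0, 0.05, 0.1, 0.2)).
#' @param reps Replicates per fraction (default 25).
#' @param span LOESS span for the GC model.
#' @return Matrix of I-scores (reps x fractions) with column means in
#'   attribute \code{means}.
#' @export
iscore_tf_battery <- function(config, tumor_fractions = c(0, 0.05, 0.1, 0.2),
                              reps = 25, span = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  base <- sim_config(seed = config$seed, genome = config$genome,
                     bin_size = config$bin_size,
                     n_controls = config$n_controls, n_patients = 0L,
                     reads_per_sample = config$reads_per_sample,
                     gc_bias = config$gc_bias, dispersion = config$dispersion,
                     cna_segments = config$cna_segments)
  sim <- simulate_bin_counts(base)
  bins <- sim$bins
  normalize_one <- function(cnt) {
    model <- fit_gc_model(cnt, sim$gc, bins, span = span)
    normalize_percent(correct_counts(cnt, model, bins), bins)
  }
  panel <- build_panel(lapply(sim$controls, normalize_one), bins)
  gcv <- sim$gc$gc
  bias <- .polyval(config$gc_bias, gcv)
  binw <- (bins$end - bins$start) / config$bin_size
  states <- sim$truth$copy_state
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  set.seed(config$seed + 1L)
  out <- matrix(NA_real_, nrow = reps, ncol = length(tumor_fractions),
                dimnames = list(NULL, paste0("tf", tumor_fractions)))
  for (r in seq_len(reps)) {
    u <- stats::runif(nrow(bins))
    for (j in seq_along(tumor_fractions)) {
      tf <- tumor_fractions[j]
      mu <- binw * bias * (1 + tf * (states - 2) / 2)
      mu <- mu * config$reads_per_sample / sum(mu)
      cnt <- if (is.finite(size)) stats::qnbinom(u, mu = mu, size = size)
             else stats::qpois(u, mu)
      bc <- bin_counts(cnt, bins, sample_id = sprintf("rep%d_tf%g", r, tf),
                       stage = "raw")
      out[r, j] <- cna_profile(normalize_one(bc), panel)$i_score
    }
  }
  attr(out, "means") <- colMeans(out)
  out
}

#' Run the full simulated pipeline: counts to instability scores
#'
#' Generates a cohort, GC-corrects and normalizes every sample, builds the
#' panel from the controls, and scores the patients.
#'
#' @param config A \code{sim_config}.
#' @param span LOESS span for the GC model (default 0.3).
#' @return List with \code{panel}, \code{profiles} (per-patient
#'   \code{cna_profile}), \code{i_scores}, \code{truth}, \code{bins}.
#' @export
simulate_cohort_scores <- function(config, span = 0.3) {
  sim <- simulate_bin_counts(config)
  normalize_one <- function(cnt) {
    model <- fit_gc_model(cnt, sim$gc, sim$bins, span = span)
    normalize_percent(correct_counts(cnt, model, sim$bins), sim$bins)
  }
  controls_n <- lapply(sim$controls, normalize_one)
  panel <- build_panel(controls_n, sim$bins)
  profiles <- lapply(sim$patients, function(p)
    cna_profile(normalize_one(p), panel))
  list(panel = panel, profiles = profiles,
       i_scores = vapply(profiles, `[[`, 0, "i_score"),
       truth = sim$truth, bins = sim$bins)
}
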