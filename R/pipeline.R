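#' Stage orchestration
#'
#' File-level wrappers used by the command-line driver
#' (\code{inst/scripts/plasma-cna.R}): each stage reads TSV/SAM/BED inputs,
#' runs the corresponding package functions, writes its outputs into an
#' output directory together with a JSON manifest (inputs, parameters,
#' seed, config hash) so a rerun with the same config is byte-reproducible.
#'
#' @name pipeline
NULL

# md5 of the canonical JSON rendering of a config list
.config_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(params[order(names(params))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(out_dir, stage, inputs, params, outputs) {
  manifest <- list(stage = stage, inputs = inputs, params = params,
                   outputs = outputs,
                   config_hash = .config_hash(c(params, inputs)),
                   package = as.character(utils::packageVersion("plasmaCNA")))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Stage: build the bin grid
#'
#' @param out_dir Output directory.
#' @param chrom_sizes Path to a chrom.sizes TSV, or \code{NULL} for hg19.
#' @param blacklist Optional BED path of excluded regions.
#' @param bin_size Bin width (default 1e6).
#' @return Path of the written bins TSV.
#' @export
stage_bins <- function(out_dir, chrom_sizes = NULL, blacklist = NULL,
                       bin_size = 1e6) {
  .ensure_dir(out_dir)
  build <- if (is.null(chrom_sizes)) hg19_build() else
    read_chrom_sizes(chrom_sizes)
  bins <- make_bins(build, bin_size)
  if (!is.null(blacklist)) bins <- apply_blacklist(bins, blacklist)
  out <- file.path(out_dir, "bins.tsv")
  write_bins(bins, out)
  .write_manifest(out_dir, "bins",
                  list(chrom_sizes = chrom_sizes, blacklist = blacklist),
                  list(bin_size = bin_size), list(bins = out))
  out
}

#' Stage: count reads per bin
#'
#' @param alignments Vector of BAM/SAM paths.
#' @param bins_tsv Bins TSV from \code{\link{stage_bins}}.
#' @param out_dir Output directory.
#' @param mapq_min Minimum MAPQ (default 60).
#' @return Paths of the written counts TSVs.
#' @export
stage_count <- function(alignments, bins_tsv, out_dir, mapq_min = 60) {
  .ensure_dir(out_dir)
  bins <- read_bins(bins_tsv)
  outs <- vapply(alignments, function(aln) {
    cnt <- count_reads(aln, bins, mapq_min = mapq_min)
    out <- file.path(out_dir, paste0(cnt$sample_id, ".counts.tsv"))
    write_counts_tsv(cnt, bins, out)
    out
  }, character(1))
  .write_manifest(out_dir, "count",
                  list(alignments = alignments, bins = bins_tsv),
                  list(mapq_min = mapq_min), as.list(outs))
  unname(outs)
}

#' Stage: build the reference panel from control counts
#'
#' GC-corrects and normalizes every control, then writes the per-bin panel
#' statistics.
#'
#' @param control_counts Vector of raw counts TSVs (controls).
#' @param gc_tsv TSV with a \code{gc} column per bin (and optionally
#'   \code{n_fraction}).
#' @param bins_tsv Bins TSV.
#' @param out_dir Output directory.
#' @param span LOESS span (default 0.3).
#' @return Path of the written panel TSV.
#' @export
stage_panel <- function(control_counts, gc_tsv, bins_tsv, out_dir,
                        span = 0.3) {
  .ensure_dir(out_dir)
  bins <- read_bins(bins_tsv)
  gc <- utils::read.table(gc_tsv, sep = "\t", header = TRUE)
  controls <- lapply(control_counts, function(p) {
    cnt <- read_counts_tsv(p, bins)
    model <- fit_gc_model(cnt, gc$gc, bins, span = span)
    normalize_percent(correct_counts(cnt, model, bins), bins)
  })
  panel <- build_panel(controls, bins)
  out <- file.path(out_dir, "panel.tsv")
  write_panel(panel, out)
  .write_manifest(out_dir, "panel",
                  list(controls = control_counts, gc = gc_tsv,
                       bins = bins_tsv),
                  list(span = span), list(panel = out))
  out
}

#' Stage: score samples against a panel
#'
#' @param sample_counts Vector of raw counts TSVs (patients).
#' @param panel_tsv Panel TSV from \code{\link{stage_panel}}.
#' @param gc_tsv GC TSV.
#' @param bins_tsv Bins TSV.
#' @param out_dir Output directory.
#' @param span LOESS span (default 0.3).
#' @param z_threshold I-score / call threshold (default 2).
#' @return Data frame of per-sample i_score and s_score; writes per-sample
#'   profile TSV/JSON and a Circos track.
#' @export
stage_score <- function(sample_counts, panel_tsv, gc_tsv, bins_tsv, out_dir,
                        span = 0.3, z_threshold = 2) {
  .ensure_dir(out_dir)
  if (!file.exists(panel_tsv))
    stop("missing prerequisite: panel file not found at ", panel_tsv,
         " (run the panel stage first)")
  bins <- read_bins(bins_tsv)
  panel <- read_panel(panel_tsv, bins)
  gc <- utils::read.table(gc_tsv, sep = "\t", header = TRUE)
  rows <- lapply(sample_counts, function(p) {
    cnt <- read_counts_tsv(p, bins)
    model <- fit_gc_model(cnt, gc$gc, bins, span = span)
    norm <- normalize_percent(correct_counts(cnt, model, bins), bins)
    prof <- cna_profile(norm, panel, threshold = z_threshold)
    base <- file.path(out_dir, paste0(prof$sample_id, ".profile.tsv"))
    write_profile(prof, base)
    write_circos_track(prof, file.path(out_dir,
                                       paste0(prof$sample_id, ".circos.tsv")))
    data.frame(sample_id = prof$sample_id, i_score = prof$i_score,
               s_score = prof$s_score)
  })
  res <- do.call(rbind, rows)
  out <- file.path(out_dir, "scores.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_manifest(out_dir, "score",
                  list(samples = sample_counts, panel = panel_tsv,
                       gc = gc_tsv, bins = bins_tsv),
                  list(span = span, z_threshold = z_threshold),
                  list(scores = out))
  res
}

#' Stage: ddPCR copy-number calls
#'
#' @param droplets_tsv Droplet counts TSV (see
#'   \code{\link{read_droplets_tsv}}).
#' @param out_dir Output directory.
#' @param control_ids Sample ids (in the TSV) that are healthy controls,
#'   used to derive the cutoff; ignored when \code{fixed_cutoff} given.
#' @param fixed_cutoff Optional fixed amplification cutoff.
#' @return Data frame of per-sample copy numbers and amplification calls.
#' @export
stage_vegfa <- function(droplets_tsv, out_dir, control_ids = NULL,
                        fixed_cutoff = NULL) {
  .ensure_dir(out_dir)
  wells <- read_droplets_tsv(droplets_tsv)
  calls <- lapply(wells, vegfa_ratio)
  ids <- vapply(calls, `[[`, "", "sample_id")
  cn <- vapply(calls, `[[`, 0, "copy_number")
  if (is.null(fixed_cutoff)) {
    if (is.null(control_ids) || sum(ids %in% control_ids) < 2L)
      stop("need >= 2 control wells (control_ids) or a fixed_cutoff")
    controls <- cn[ids %in% control_ids]
  } else controls <- NULL
  calls <- lapply(calls, amplification_call, control_values = controls,
                  fixed_cutoff = fixed_cutoff)
  res <- data.frame(sample_id = ids,
                    lambda_target = vapply(calls, `[[`, 0, "lambda_target"),
                    lambda_ref = vapply(calls, `[[`, 0, "lambda_ref"),
                    copy_number = cn,
                    cutoff = vapply(calls, `[[`, 0, "cutoff"),
                    amplified = vapply(calls, `[[`, NA, "amplified"),
                    is_control = ids %in% (control_ids %||% character(0)))
  out <- file.path(out_dir, "vegfa.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res, file.path(out_dir, "vegfa.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_manifest(out_dir, "vegfa", list(droplets = droplets_tsv),
                  list(control_ids = control_ids,
                       fixed_cutoff = fixed_cutoff), list(vegfa = out))
  res
}

#' Stage: biomarker survival report
#'
#' Median-dichotomizes each biomarker, runs Kaplan-Meier + log-rank per
#' endpoint, and Cox models (univariable screening then multivariable).
#'
#' @param cohort_tsv Clinical TSV (see \code{\link{read_cohort_tsv}}).
#' @param out_dir Output directory.
#' @param biomarkers Biomarker column names to dichotomize.
#' @param covariates Additional covariate column names for the Cox models.
#' @param endpoints Endpoint prefixes (default c("ttp", "os")); each needs
#'   \code{<p>_time} and \code{<p>_event} columns.
#' @return Nested list of results per endpoint; writes TSV + JSON.
#' @export
stage_survival <- function(cohort_tsv, out_dir, biomarkers,
                           covariates = character(0),
                           endpoints = c("ttp", "os")) {
  .ensure_dir(out_dir)
  cohort <- read_cohort_tsv(cohort_tsv)
  for (bm in biomarkers)
    cohort[[paste0(bm, "_group")]] <- dichotomize_median(cohort[[bm]])
  group_cols <- paste0(biomarkers, "_group")
  results <- list()
  rows <- list()
  for (ep in endpoints) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(cohort))) next
    ep_res <- list()
    for (gc in group_cols) {
      km <- km_estimate(cohort[[tcol]], cohort[[ecol]], cohort[[gc]])
      lr <- logrank(cohort[[tcol]], cohort[[ecol]], cohort[[gc]])
      ep_res[[gc]] <- list(km_median = km$median, logrank = lr)
      for (r in seq_len(nrow(km$median)))
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, variable = gc, group = km$median$group[r],
          n = km$median$n[r], events = km$median$events[r],
          median = km$median$median[r], ci_low = km$median$ci_low[r],
          ci_high = km$median$ci_high[r], logrank_p = lr$p)
    }
    cox <- cox_fit(cohort, tcol, ecol, c(group_cols, covariates),
                   mode = "multivariable")
    ep_res$cox <- cox
    results[[ep]] <- ep_res
  }
  med_df <- do.call(rbind, rows)
  utils::write.table(med_df, file.path(out_dir, "km_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cox_df <- do.call(rbind, lapply(names(results), function(ep)
    cbind(endpoint = ep, as.data.frame(results[[ep]]$cox))))
  utils::write.table(cox_df, file.path(out_dir, "cox.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(km = med_df, cox = cox_df),
                       file.path(out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_manifest(out_dir, "survival", list(cohort = cohort_tsv),
                  list(biomarkers = biomarkers, covariates = covariates,
                       endpoints = endpoints),
                  list(km = file.path(out_dir, "km_medians.tsv"),
                       cox = file.path(out_dir, "cox.tsv")))
  results
}

#' Stage: simulate a full synthetic input set
#'
#' Writes bins, GC track, control and patient counts, droplet counts, a
#' clinical table and the ground truth into \code{out_dir}, in exactly the
#' schemas the other stages consume.
#'
#' @param out_dir Output directory.
#' @param config A \code{sim_config} (default \code{sim_config()}).
#' @return Invisible list of written paths.
#' @export
stage_simulate <- function(out_dir, config = sim_config()) {
  .ensure_dir(out_dir)
  sim <- simulate_bin_counts(config)
  bins_path <- file.path(out_dir, "bins.tsv")
  write_bins(sim$bins, bins_path)
  gc_path <- file.path(out_dir, "gc.tsv")
  utils::write.table(as.data.frame(sim$gc), gc_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_all <- function(lst) vapply(lst, function(cnt) {
    p <- file.path(out_dir, paste0(cnt$sample_id, ".counts.tsv"))
    write_counts_tsv(cnt, sim$bins, p)
    p
  }, character(1))
  ctl_paths <- write_all(sim$controls)
  pat_paths <- write_all(sim$patients)
  # droplet wells: patients + controls
  droplet_rows <- do.call(rbind, lapply(seq_len(config$n_patients), function(i) {
    d <- simulate_droplets(config$n_droplets, config$true_copy_number,
                           config$reference_lambda,
                           seed = config$seed + 1000L + i,
                           sample_id = sprintf("patient_%02d", i))
    data.frame(sample_id = d$sample_id, k_target = d$k_target,
               n_target = d$n_target, k_ref = d$k_ref, n_ref = d$n_ref)
  }))
  droplets_path <- file.path(out_dir, "droplets.tsv")
  if (!is.null(droplet_rows))
    utils::write.table(droplet_rows, droplets_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(tumor_fraction = sim$truth$tumor_fraction,
                            copy_state = sim$truth$copy_state,
                            segments = sim$truth$segments,
                            seed = config$seed),
                       truth_path, auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "simulate", list(),
                  list(seed = config$seed,
                       genome = attr(config$genome, "name"),
                       n_controls = config$n_controls,
                       n_patients = config$n_patients,
                       group_hr = config$group_hr),
                  list(bins = bins_path, gc = gc_path,
                       droplets = droplets_path, truth = truth_path))
  invisible(list(bins = bins_path, gc = gc_path, controls = ctl_paths,
                 patients = pat_paths, droplets = droplets_path,
                 truth = truth_path))
}
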