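test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_patients = 2)
  a <- simulate_bin_counts(cfg)
  b <- simulate_bin_counts(cfg)
  expect_identical(lapply(a$controls, `[[`, "counts"),
                   lapply(b$controls, `[[`, "counts"))
  expect_identical(lapply(a$patients, `[[`, "counts"),
                   lapply(b$patients, `[[`, "counts"))
  d1 <- simulate_droplets(5000, 3, 0.2, seed = 7)
  d2 <- simulate_droplets(5000, 3, 0.2, seed = 7)
  expect_identical(d1, d2)
  g <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  expect_identical(simulate_survival(g, seed = 7), simulate_survival(g, seed = 7))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(tumor_fraction = 1), "tumor_fraction")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(n_controls = 1), "n_controls")
  seg <- data.frame(chrom = "chrA", start = 0, end = 1e6, copy_state = 2)
  expect_error(sim_config(cna_segments = seg), "copy_state")
  expect_error(simulate_survival(rep("a", 4), censoring_rate = 1),
               "censoring_rate")
})

test_that("tumor-fraction-zero patients are exchangeable with controls", {
  for (s in c(61, 62)) {
    cfg <- sim_config(seed = s, n_controls = 20, n_patients = 10,
                      tumor_fraction = 0)
    sim <- simulate_bin_counts(cfg)
    norm <- function(x) normalize_sample(x, sim$gc, sim$bins)
    ctl_norm <- lapply(sim$controls, norm)
    # panel from the first 12 controls; the held-out 8 controls and the
    # tf = 0 patients are both out-of-panel, hence exchangeable
    panel <- build_panel(ctl_norm[1:12], sim$bins)
    held_scores <- vapply(ctl_norm[13:20], function(x)
      cna_profile(x, panel)$i_score, 0)
    pat_scores <- vapply(sim$patients, function(p)
      cna_profile(norm(p), panel)$i_score, 0)
    expect_gt(stats::wilcox.test(held_scores, pat_scores)$p.value, 0.01)
  }
})

test_that("a whole-chromosome 3-copy gain at tf 0.5 lifts counts by 1.25x", {
  build <- toy_build(3L, 30L)
  seg <- data.frame(chrom = "chrA", start = 0, end = 30e6, copy_state = 3)
  cfg <- sim_config(seed = 63, genome = build, n_patients = 1,
                    tumor_fraction = 0.5, cna_segments = seg,
                    reads_per_sample = 90 * 5e4, dispersion = 0)
  sim <- simulate_bin_counts(cfg)
  st <- sim$truth$copy_state
  # normalize out the GC bias using the generator's own bias bookkeeping
  rel <- sim$patients[[1]]$counts / sim$truth$gc_bias
  ratio <- mean(rel[st == 3]) / mean(rel[st == 2])
  expect_lt(abs(ratio / 1.25 - 1), 0.03)
})

test_that("mean I-score increases strictly with tumor fraction", {
  battery <- iscore_tf_battery(sim_config(seed = 64), reps = 25)
  means <- attr(battery, "means")
  expect_length(means, 4L)
  expect_true(all(diff(means) > 0))
})

test_that("survival generator honors censoring and hazard settings", {
  g <- factor(rep(c("low", "high"), each = 100), levels = c("low", "high"))
  # no censoring: every subject has the event
  df0 <- simulate_survival(g, censoring_rate = 0, seed = 65)
  expect_true(all(df0$ttp_event == 1) && all(df0$os_event == 1))

  # stated censoring rate is hit in expectation
  df3 <- simulate_survival(g, censoring_rate = 0.3, frailty_sd = 0, seed = 65)
  expect_lt(abs(mean(1 - df3$os_event) - 0.3), 0.12)

  # null hazard ratio: log-rank rejects at about the nominal level
  p <- vapply(1:200, function(s) {
    d <- simulate_survival(g, group_hr = 1, censoring_rate = 0.2,
                           frailty_sd = 0, seed = 1000 + s)
    logrank(d$os_time, d$os_event, d$group)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(p) - 0.05), 0.045)

  # hazard ratio 3.5 is recovered within the fitted CI (fixed seed)
  d <- simulate_survival(g, group_hr = 3.5, censoring_rate = 0.2,
                         frailty_sd = 0, seed = 66)
  f <- cox_fit(cbind(d, grp = d$group), "os_time", "os_event", "grp",
               mode = "univariable")
  expect_true(f$ci_low <= 3.5 && 3.5 <= f$ci_high)
})

test_that("the toy pipeline runs end-to-end from SAM to I-scores", {
  # small cohort through the full path: simulate counts, realize one
  # patient as SAM, count it back, GC-correct, score
  cfg <- sim_config(seed = 67, genome = toy_build(2L, 30L),
                    n_patients = 1, tumor_fraction = 0.3,
                    reads_per_sample = 60 * 300)
  sim <- simulate_bin_counts(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_sam(sim$patients[[1]], sim$bins, sam, n_decoys = 10, seed = 67)
  recounted <- count_reads(sam, sim$bins)
  expect_equal(recounted$counts, sim$patients[[1]]$counts)

  ctl_norm <- lapply(sim$controls, normalize_sample, gc = sim$gc,
                     bins = sim$bins)
  panel <- build_panel(ctl_norm, sim$bins)
  prof <- cna_profile(normalize_sample(recounted, sim$gc, sim$bins), panel)
  expect_s3_class(prof, "cna_profile")
  expect_gte(prof$i_score, 0)
})
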