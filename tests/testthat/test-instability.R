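test_that("build_panel computes per-bin mean and sample SD", {
  bins <- tiny_bins(4L)
  controls <- list(control_with_bin1(1.0, bins, "c1"),
                   control_with_bin1(1.2, bins, "c2"),
                   control_with_bin1(1.4, bins, "c3"))
  panel <- build_panel(controls, bins)
  expect_equal(panel$n_controls, 3L)
  expect_equal(panel$mean_pct[1], 1.2)
  expect_equal(panel$sd_pct[1], 0.2)  # n-1 denominator
  # population SD switch
  pop <- build_panel(controls, bins, sd_type = "population")
  expect_equal(pop$sd_pct[1], 0.2 * sqrt(2 / 3))
  # means over usable bins sum to 100
  expect_equal(sum(panel$mean_pct[bins$usable]), 100, tolerance = 1e-6)
})

test_that("identical controls give a fully unscorable panel", {
  bins <- tiny_bins(4L)
  ctl <- control_with_bin1(1.0, bins)
  expect_message(panel <- build_panel(list(ctl, ctl, ctl), bins),
                 "zero panel SD")
  expect_false(any(panel$scorable))
})

test_that("build_panel validates its inputs", {
  bins <- tiny_bins(4L)
  expect_error(build_panel(list(control_with_bin1(1, bins)), bins),
               "at least 2")
  raw <- bin_counts(rep(1, 4), bins, stage = "raw")
  expect_error(build_panel(list(raw, raw), bins), "normalized_percent")
  other <- tiny_bins(5L)
  expect_error(build_panel(list(control_with_bin1(1, bins),
                                control_with_bin1(1, other)), bins),
               "different bin set")
})

test_that("panel means sum to 100 across random simulated panels", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(6:30, 1)
    bins <- tiny_bins(n)
    controls <- lapply(1:4, function(i) {
      v <- stats::runif(n, 10, 100)
      bin_counts(100 * v / sum(v), bins, sample_id = paste0("c", i),
                 stage = "normalized_percent")
    })
    panel <- build_panel(controls, bins)
    expect_equal(sum(panel$mean_pct), 100, tolerance = 1e-6)
  }
})

test_that("zscores standardize against the panel", {
  bins <- tiny_bins(4L)
  # controls engineered so bin 1 has mean 1.0, SD 0.1
  controls <- list(control_with_bin1(0.9, bins), control_with_bin1(1.0, bins),
                   control_with_bin1(1.1, bins))
  panel <- build_panel(controls, bins)
  expect_equal(panel$mean_pct[1], 1.0)
  expect_equal(panel$sd_pct[1], 0.1)

  # sample equal to panel means: z identically 0
  mean_sample <- bin_counts(panel$mean_pct, bins, sample_id = "mean",
                            stage = "normalized_percent")
  expect_equal(zscores(mean_sample, panel), rep(0, 4))

  # pct 1.2 against mean 1.0, SD 0.1 gives z = 2
  s <- control_with_bin1(1.2, bins, "s")
  expect_equal(zscores(s, panel)[1], 2.0)
})

test_that("zscores match a brute-force recomputation on a random fixture", {
  set.seed(42)
  n <- 20L
  bins <- tiny_bins(n)
  controls <- lapply(1:6, function(i) {
    v <- stats::runif(n, 10, 100)
    bin_counts(100 * v / sum(v), bins, sample_id = paste0("c", i),
               stage = "normalized_percent")
  })
  panel <- build_panel(controls, bins)
  v <- stats::runif(n, 10, 100)
  s <- bin_counts(100 * v / sum(v), bins, sample_id = "s",
                  stage = "normalized_percent")
  z <- zscores(s, panel)
  # loop oracle
  mat <- sapply(controls, function(x) x$counts)
  for (j in seq_len(n)) {
    m <- mean(mat[j, ]); sd_j <- stats::sd(mat[j, ])
    expect_equal(z[j], (s$counts[j] - m) / sd_j)
  }
})

test_that("i_score sums |z| beyond the strict threshold", {
  expect_equal(i_score(c(2.5, -3.0, 1.9, -1.5, 2.0)), 5.5)
  expect_equal(i_score(rep(0, 10)), 0)
  expect_equal(i_score(c(2, -2, 1.99, -1.99)), 0)   # strictness
  expect_equal(i_score(numeric(0)), 0)
  expect_equal(i_score(c(NA, 2.5)), 2.5)            # NA bins ignored
  expect_equal(i_score(c(3, -3), threshold = 2.5), 6)
})

test_that("i_score equals a per-element loop oracle on random inputs", {
  set.seed(43)
  for (rep in 1:50) {
    z <- stats::rnorm(sample(1:200, 1), sd = stats::runif(1, 0.5, 3))
    t <- stats::runif(1, 0.5, 3)
    oracle <- 0
    for (zz in z) if (abs(zz) > t) oracle <- oracle + abs(zz)
    expect_equal(i_score(z, t), oracle)
  }
})

test_that("i_score is monotone in |z| and unaffected by sub-threshold bins", {
  set.seed(44)
  z <- stats::rnorm(50, sd = 2)
  base <- i_score(z)
  for (rep in 1:20) {
    j <- sample(50, 1)
    z2 <- z
    z2[j] <- z2[j] * 1.5
    expect_gte(i_score(z2), base - 1e-12)
  }
  expect_equal(i_score(c(z, stats::runif(30, -2, 2))), base)
})

test_that("s_score sums all squared z and bounds the thresholded square sum", {
  expect_equal(s_score(rep(0, 5)), 0)
  expect_equal(s_score(c(1, 2)), 5)
  set.seed(45)
  for (rep in 1:20) {
    z <- stats::rnorm(100, sd = 1.5)
    expect_gte(s_score(z), sum(z[abs(z) > 2]^2))
    expect_equal(s_score(z), sum(z^2))
  }
})

test_that("call_cna uses strict thresholds consistent with the I-score", {
  expect_equal(call_cna(c(2.4, -2.4, 2.0, -2.0, 0, NA)),
               c("gain", "loss", "neutral", "neutral", "neutral", NA))
})

test_that("a held-out control scores far below tumor-fraction samples", {
  cfg <- sim_config(seed = 3, n_patients = 4, tumor_fraction = 0.2)
  sim <- simulate_bin_counts(cfg)
  ctl <- lapply(sim$controls, normalize_sample, gc = sim$gc, bins = sim$bins)
  panel_rest <- build_panel(ctl[-1], sim$bins)
  held_out <- cna_profile(ctl[[1]], panel_rest)$i_score
  patient_scores <- vapply(sim$patients, function(p)
    cna_profile(normalize_sample(p, sim$gc, sim$bins), panel_rest)$i_score, 0)
  expect_true(all(patient_scores > 2 * held_out))
})

test_that("cna_profile bundles scores, calls and methods", {
  bins <- tiny_bins(4L)
  controls <- list(control_with_bin1(0.9, bins), control_with_bin1(1.0, bins),
                   control_with_bin1(1.1, bins))
  panel <- build_panel(controls, bins)
  prof <- cna_profile(control_with_bin1(1.25, bins, "pt"), panel)
  expect_s3_class(prof, "cna_profile")
  expect_equal(prof$calls[1], "gain")          # z = 2.5
  expect_equal(prof$i_score, i_score(prof$z))
  expect_equal(prof$s_score, s_score(prof$z))
  expect_output(print(prof), "I-score")
  smry <- summary(prof)
  expect_equal(smry$gain, sum(prof$calls == "gain", na.rm = TRUE))
  # plot renders without error to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(prof))
})

test_that("panel and profile serialization round-trip", {
  bins <- tiny_bins(6L)
  set.seed(46)
  controls <- lapply(1:3, function(i) {
    v <- stats::runif(6, 10, 100)
    bin_counts(100 * v / sum(v), bins, sample_id = paste0("c", i),
               stage = "normalized_percent")
  })
  panel <- build_panel(controls, bins)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path, bins)
  expect_equal(back$mean_pct, panel$mean_pct)
  expect_equal(back$sd_pct, panel$sd_pct)
  expect_equal(back$n_controls, panel$n_controls)

  prof <- cna_profile(controls[[1]], panel)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, ppath)
  js <- jsonlite::read_json(paste0(ppath, ".json"))
  expect_equal(js$i_score, prof$i_score)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_circos_track(prof, cpath)
  tr <- utils::read.table(cpath, header = TRUE)
  expect_equal(nrow(tr), sum(!is.na(prof$z)))
})
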