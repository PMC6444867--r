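test_that("dcr counts disease control responses", {
  # the printed worked example: 0 CR + 2 PR + 94 SD/non-CR-non-PD of 151
  resp <- c(rep("PR", 2), rep("SD", 60), rep("nonCRnonPD", 34),
            rep("PD", 53), rep("NE", 2))
  out <- dcr(resp)
  expect_equal(out$n, 151L)
  expect_equal(out$n_controlled, 96L)
  expect_equal(round(out$dcr, 1), 63.6)

  expect_equal(dcr(rep("PD", 10))$dcr, 0)
  expect_equal(dcr(rep("CR", 10))$dcr, 100)
  expect_error(dcr(character(0)), "no subjects")
  expect_error(dcr(c("CR", "bogus")), "bogus")
})

test_that("elevated_fraction reproduces the Wald interval arithmetic", {
  # 122 of 151 strictly above the controls' 90th percentile
  controls <- seq(0.28, 0.54, length.out = 14)
  thr <- unname(stats::quantile(controls, 0.9))
  values <- c(rep(thr + 0.1, 122), rep(thr - 0.1, 29))
  out <- elevated_fraction(values, controls)
  expect_equal(out$n_elevated, 122L)
  expect_equal(round(out$fraction, 1), 80.8)
  expect_equal(round(out$ci, 1), c(74.5, 87.1))

  # independent arithmetic oracle for the interval
  p <- 122 / 151
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / 151)
  expect_equal(out$ci, 100 * c(p - half, p + half), tolerance = 1e-9)

  # boundary cases
  expect_equal(elevated_fraction(rep(thr - 1, 5), controls)$fraction, 0)
  # a value exactly at the threshold is not elevated (strictly above)
  expect_equal(elevated_fraction(c(thr), controls)$n_elevated, 0L)

  # Wald interval stays close to the exact binomial interval at moderate N
  exact <- stats::binom.test(122, 151)$conf.int * 100
  expect_lt(max(abs(out$ci - exact)), 2)
})

test_that("dichotomize_median sends ties to the low group", {
  g <- dichotomize_median(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutpoint"), 2.5)

  # a value exactly at the median is low
  g2 <- dichotomize_median(c(1, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "high"))

  # 151 distinct values split 76 low / 75 high
  set.seed(51)
  v <- sample(stats::runif(151))
  g3 <- dichotomize_median(v)
  expect_equal(unname(table(g3)["low"]), 76L)
  expect_equal(unname(table(g3)["high"]), 75L)

  # balance property for distinct values
  for (n in c(10, 11, 57)) {
    gg <- dichotomize_median(stats::runif(n))
    expect_lte(abs(diff(table(gg))), 1)
  }
  expect_warning(dichotomize_median(rep(1, 5)), "identical")
})

test_that("quartile_groups assign boundaries to the lower group", {
  q <- quartile_groups(1:8)
  expect_equal(as.vector(table(q)), c(2L, 2L, 2L, 2L))

  # 151 distinct values: sizes are a permutation of (38, 38, 38, 37)
  set.seed(52)
  v <- stats::rnorm(151)
  q2 <- quartile_groups(v)
  expect_setequal(as.vector(table(q2)), c(38L, 38L, 38L, 37L))
  expect_equal(sum(table(q2)), 151L)

  # rank invariance under monotone relabeling
  q3 <- quartile_groups(exp(v))
  expect_equal(as.character(q2), as.character(q3))

  expect_error(quartile_groups(1:3), "4 values")
  expect_warning(quartile_groups(c(1, 1, 1, 1, 1, 9)), "ties")
})

test_that("km_estimate matches the product-limit construction", {
  # five events, no censoring: steps of 1/5 and median at the third time
  out <- km_estimate(1:5, rep(1, 5))
  expect_equal(out$fit$surv, seq(0.8, 0, by = -0.2))
  expect_equal(out$median$median, 3)

  # all censored: survival stays 1, median not reached
  out2 <- km_estimate(1:5, rep(0, 5))
  expect_true(all(out2$fit$surv == 1))
  expect_true(is.na(out2$median$median))

  # brute-force product over risk sets on a random fixture
  set.seed(53)
  times <- round(stats::rexp(40, 0.2), 3)
  events <- stats::rbinom(40, 1, 0.7)
  fit <- km_estimate(times, events)$fit
  ts <- fit$time
  surv_oracle <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv_oracle[i] <- s
  }
  expect_equal(fit$surv, surv_oracle, tolerance = 1e-12)
})

test_that("logrank matches hand-computed risk-table arithmetic", {
  # duplicated data in both groups: statistic exactly 0
  times <- c(1, 2, 3, 1, 2, 3)
  events <- rep(1, 6)
  groups <- rep(c("a", "b"), each = 3)
  expect_equal(logrank(times, events, groups)$chisq, 0, tolerance = 1e-12)

  # six-subject worked fixture, alternating event times:
  # O_A = 3, E_A = 2.2333, V = 1.21222 -> chisq = 0.48489
  lr <- logrank(c(1, 3, 5, 2, 4, 6), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, (3 - (0.5 + 0.4 + 0.5 + 1 / 3 + 0.5))^2 /
                 (0.25 + 0.24 + 0.25 + 2 / 9 + 0.25), tolerance = 1e-6)
  expect_equal(lr$p, stats::pchisq(lr$chisq, 1, lower.tail = FALSE))

  # invariant under group relabeling
  lr2 <- logrank(c(1, 3, 5, 2, 4, 6), rep(1, 6), rep(c("B", "A"), each = 3))
  expect_equal(lr2$chisq, lr$chisq)

  expect_error(logrank(1:3, c(1, 1, 1), rep("a", 3)), "2 nonempty")
})

test_that("logrank holds its size under the null", {
  set.seed(54)
  reject <- vapply(1:400, function(i) {
    t <- stats::rexp(60, 0.2)
    e <- stats::rbinom(60, 1, 0.8)
    g <- rep(c("a", "b"), 30)
    logrank(t, e, g)$p < 0.05
  }, logical(1))
  rate <- mean(reject)
  mcse <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 2.5 * mcse + 0.01)
})

test_that("cox_fit recovers a generating hazard ratio of 3.5", {
  groups <- factor(rep(c("low", "high"), each = 75), levels = c("low", "high"))
  df <- simulate_survival(groups, group_hr = 3.5, censoring_rate = 0.3,
                          frailty_sd = 0, seed = 55)
  expect_gt(mean(df$os_event), 0.6)
  fit <- cox_fit(cbind(df, grp = df$group), "os_time", "os_event", "grp",
                 mode = "univariable")
  expect_gt(fit$hr, 2.4)
  expect_lt(fit$hr, 5.2)
})

test_that("a covariate independent of hazard has CI covering 1", {
  cover <- vapply(1:100, function(s) {
    set.seed(500 + s)
    n <- 80
    noise <- stats::rnorm(n)
    t <- stats::rexp(n, 0.2)
    e <- stats::rbinom(n, 1, 0.8)
    f <- cox_fit(data.frame(t = t, e = e, x = noise), "t", "e", "x",
                 mode = "univariable")
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(sum(cover), 93)
})

test_that("duplicating every subject leaves the Cox point estimate unchanged", {
  groups <- factor(rep(c("low", "high"), each = 40), levels = c("low", "high"))
  df <- simulate_survival(groups, group_hr = 2, censoring_rate = 0.2,
                          frailty_sd = 0, seed = 56)
  df$grp <- df$group
  # exact invariance holds for the Breslow tie approximation (duplication
  # creates ties of size two at every event time)
  f1 <- cox_fit(df, "os_time", "os_event", "grp", mode = "univariable",
                ties = "breslow")
  f2 <- cox_fit(rbind(df, df), "os_time", "os_event", "grp",
                mode = "univariable", ties = "breslow")
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)
  # Efron (the default) perturbs the estimate only slightly
  e1 <- cox_fit(df, "os_time", "os_event", "grp", mode = "univariable")
  e2 <- cox_fit(rbind(df, df), "os_time", "os_event", "grp",
                mode = "univariable")
  expect_equal(e1$hr, e2$hr, tolerance = 0.02)
})

test_that("multivariable mode screens covariates univariably first", {
  set.seed(57)
  n <- 150
  grp <- factor(rep(c("low", "high"), each = n / 2),
                levels = c("low", "high"))
  df <- simulate_survival(grp, group_hr = 3, censoring_rate = 0.2,
                          frailty_sd = 0, seed = 57)
  df$biomarker <- df$group
  df$junk <- stats::rnorm(n)      # independent of hazard
  out <- cox_fit(df, "os_time", "os_event", c("biomarker", "junk"),
                 mode = "multivariable")
  expect_true("biomarker" %in% attr(out, "selected"))
  expect_false("junk" %in% attr(out, "selected"))
  expect_true(any(out$mode == "multivariable"))
})

test_that("cohort TSVs validate ids, times and event flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b"), i_score = c(100, 2000),
                   ttp_time = c(2.2, 4.1), ttp_event = c(1, 0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cohort_tsv(path)
  expect_equal(back$i_score, df$i_score)

  bad <- df
  bad$id <- c("a", "a")
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort_tsv(path), "duplicate")

  bad2 <- df
  bad2$ttp_event <- c(2, 0)
  utils::write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort_tsv(path), "0/1")
})
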