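#' Downstream biomarker statistics
#'
#' Response and survival analyses for cfDNA biomarkers: disease control
#' rate, the elevated-versus-healthy-controls rule, median and quartile
#' grouping, Kaplan-Meier estimation, the log-rank test and proportional
#' hazards modelling (univariable screening followed by a multivariable
#' model).  Time-to-event machinery is delegated to the survival package;
#' the grouping and screening conventions are defined here.
#'
#' @name survival_biomarker
NULL

.RESPONSE_LEVELS <- c("CR", "PR", "SD", "nonCRnonPD", "PD", "NE")
.CONTROL_RESPONSES <- c("CR", "PR", "SD", "nonCRnonPD")

#' Disease control rate
#'
#' Percentage of subjects whose best response is CR, PR, SD or
#' non-CR/non-PD, with a 95% Wald confidence interval.
#'
#' @param best_response Character vector of best responses (levels CR, PR,
#'   SD, nonCRnonPD, PD, NE).
#' @param conf_level Confidence level (default 0.95).
#' @return List with \code{n}, \code{n_controlled}, \code{dcr} (percent)
#'   and \code{ci} (percent, length 2).
#' @export
#' @examples
#' dcr(c(rep("PR", 2), rep("SD", 94), rep("PD", 55)))$dcr  # 63.6%
dcr <- function(best_response, conf_level = 0.95) {
  n <- length(best_response)
  if (n == 0L) stop("no subjects")
  bad <- !(best_response %in% .RESPONSE_LEVELS)
  if (any(bad))
    stop("unknown best response value(s): ",
         paste(unique(best_response[bad]), collapse = ", "))
  k <- sum(best_response %in% .CONTROL_RESPONSES)
  p <- k / n
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zc * sqrt(p * (1 - p) / n)
  list(n = n, n_controlled = k, dcr = 100 * p,
       ci = 100 * c(max(0, p - half), min(1, p + half)))
}

#' Fraction of subjects elevated above healthy controls
#'
#' Fraction of subject values strictly above the stated percentile of the
#' healthy-control distribution, with a Wald 95% CI
#' p +/- 1.96 sqrt(p(1-p)/N).
#'
#' @param values Subject biomarker values.
#' @param controls Healthy-control values (nonempty).
#' @param percentile Control percentile defining "elevated" (default 90).
#' @param conf_level Confidence level (default 0.95).
#' @return List with \code{threshold}, \code{n}, \code{n_elevated},
#'   \code{fraction} (percent) and \code{ci} (percent).
#' @export
elevated_fraction <- function(values, controls, percentile = 90,
                              conf_level = 0.95) {
  if (length(controls) == 0L) stop("no control values")
  if (length(values) == 0L) stop("no subject values")
  thr <- unname(stats::quantile(controls, percentile / 100))
  k <- sum(values > thr)
  n <- length(values)
  p <- k / n
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zc * sqrt(p * (1 - p) / n)
  list(threshold = thr, n = n, n_elevated = k, fraction = 100 * p,
       ci = 100 * c(max(0, p - half), min(1, p + half)))
}

#' Median dichotomization into low/high groups
#'
#' low iff value <= median (midpoint-interpolated for even N), high
#' otherwise.  Ties at the median go to the low group, matching the usual
#' "<= median" / "> median" table rows.  For an odd number of distinct
#' values this yields (n+1)/2 low and (n-1)/2 high.
#'
#' @param values Numeric vector (>= 2 values).
#' @return Factor with levels \code{low}, \code{high}; the median is
#'   attached as attribute \code{cutpoint}.
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  med <- stats::median(values)
  if (all(values == values[1]))
    warning("all values identical; every subject assigned to the low group")
  out <- factor(ifelse(values <= med, "low", "high"),
                levels = c("low", "high"))
  attr(out, "cutpoint") <- med
  out
}

#' Quartile grouping
#'
#' Groups by the 25th/50th/75th percentiles; values exactly on a boundary
#' go to the lower quartile, consistent with the median rule.  Rank
#' invariant: any strictly monotone relabeling of the values leaves the
#' groups unchanged.
#'
#' @param values Numeric vector (>= 4 values).
#' @return Factor with levels \code{Q1} (lowest) .. \code{Q4} (highest);
#'   the cutpoints are attached as attribute \code{cutpoints}.
#' @export
quartile_groups <- function(values) {
  if (length(values) < 4L) stop("need >= 4 values")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75))
  lab <- ifelse(values <= qs[1], "Q1",
                ifelse(values <= qs[2], "Q2",
                       ifelse(values <= qs[3], "Q3", "Q4")))
  out <- factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
  if (any(table(out) == 0L))
    warning("heavy ties collapsed at least one quartile group")
  attr(out, "cutpoints") <- unname(qs)
  out
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator via \code{survival::survfit} with log-log
#' confidence intervals.  The median is the earliest time at which the
#' survival curve drops to 0.5 or below; with no events (or a curve that
#' never reaches 0.5) the median is not reached and reported as \code{NA}.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Optional grouping factor for stratified curves.
#' @param conf_level Confidence level (default 0.95).
#' @return List with the \code{survfit} object (\code{fit}) and a data
#'   frame \code{median} (group, n, events, median, ci_low, ci_high).
#' @export
km_estimate <- function(times, events, groups = NULL, conf_level = 0.95) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  df <- data.frame(time = times, event = events)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                             conf.type = "log-log", conf.int = conf_level)
  } else {
    df$group <- groups
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                             conf.type = "log-log", conf.int = conf_level)
  }
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  med <- data.frame(group = sub("^group=", "", rownames(tab)),
                    n = tab[, "records"], events = tab[, "events"],
                    median = tab[, "median"],
                    ci_low = tab[, grep("LCL", colnames(tab))],
                    ci_high = tab[, grep("UCL", colnames(tab))],
                    row.names = NULL)
  list(fit = fit, median = med)
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square over the pooled event
#' times, via \code{survival::survdiff}.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Grouping factor (>= 2 nonempty groups).
#' @return List with \code{chisq}, \code{df} and two-sided \code{p}.
#' @export
logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 nonempty groups")
  df <- data.frame(time = times, event = events, group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n) - 1
  list(chisq = sd$chisq, df = k, p = stats::pchisq(sd$chisq, k,
                                                   lower.tail = FALSE))
}

#' Proportional hazards fits with univariable screening
#'
#' Univariable mode fits one Cox model per covariate.  Multivariable mode
#' mirrors the common biomarker workflow: every covariate is screened
#' univariably, and those with Wald p < \code{alpha} enter a joint model.
#' Ties use the Efron approximation.
#'
#' @param data Data frame with one row per subject.
#' @param time,event Column names of the endpoint's time and indicator.
#' @param covariates Character vector of covariate column names.
#' @param mode \code{"univariable"} or \code{"multivariable"}.
#' @param alpha Univariable screening threshold for entry into the
#'   multivariable model (default 0.05).
#' @param ties Tie-handling approximation passed to
#'   \code{survival::coxph} (default \code{"efron"}).
#' @return A data frame with one row per fitted coefficient: covariate,
#'   term, HR, ci_low, ci_high, p, and (multivariable) which covariates
#'   were selected; attribute \code{fits} keeps the \code{coxph} objects.
#' @export
cox_fit <- function(data, time, event, covariates,
                    mode = c("univariable", "multivariable"), alpha = 0.05,
                    ties = "efron") {
  mode <- match.arg(mode)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  n_events <- sum(data[[event]])
  surv_str <- sprintf("survival::Surv(%s, %s)", time, event)

  tidy_fit <- function(fit, covs) {
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(term = rownames(co), hr = unname(co[, "exp(coef)"]),
               ci_low = unname(ci[, 3]), ci_high = unname(ci[, 4]),
               p = unname(co[, "Pr(>|z|)"]), row.names = NULL)
  }

  fit_one <- function(covs) {
    f <- stats::as.formula(paste(surv_str, "~", paste(covs, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = ties)
    if (!is.null(fit$coefficients) && anyNA(fit$coefficients))
      stop("Cox model did not converge (NA coefficients); check for ",
           "separation or collinearity in: ", paste(covs, collapse = ", "))
    fit
  }

  if (n_events < length(covariates) + 1 && mode == "multivariable")
    stop("too few events (", n_events, ") for a multivariable model with ",
         length(covariates), " covariates")

  uni <- lapply(covariates, function(cv) {
    fit <- fit_one(cv)
    cbind(covariate = cv, tidy_fit(fit), mode = "univariable")
  })
  uni_df <- do.call(rbind, uni)
  if (mode == "univariable") {
    attr(uni_df, "fits") <- NULL
    return(uni_df)
  }
  # screen: a covariate enters if any of its terms has p < alpha
  sel <- unique(uni_df$covariate[uni_df$p < alpha])
  if (length(sel) == 0L) {
    warning("no covariate passed univariable screening at alpha = ", alpha)
    out <- uni_df
    attr(out, "selected") <- character(0)
    return(out)
  }
  multi_fit <- fit_one(sel)
  multi_df <- cbind(covariate = rep(sel, vapply(sel, function(cv)
    sum(grepl(paste0("^", cv), rownames(summary(multi_fit)$coefficients))),
    1L)), tidy_fit(multi_fit), mode = "multivariable")
  out <- rbind(uni_df, multi_df)
  attr(out, "selected") <- sel
  attr(out, "fit") <- multi_fit
  out
}

#' Read a clinical cohort TSV
#'
#' One row per subject.  Required columns: \code{id}; any biomarker or
#' covariate columns; optionally \code{best_response}; per endpoint a
#' \code{<endpoint>_time} / \code{<endpoint>_event} pair (e.g.
#' \code{ttp_time}, \code{ttp_event}, \code{os_time}, \code{os_event}).
#'
#' @param path TSV path.
#' @return Data frame; validates unique ids, non-negative times, binary
#'   event indicators.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("cohort TSV needs an 'id' column: ", path)
  if (anyDuplicated(df$id)) stop("duplicate subject ids in ", path)
  for (cn in grep("_time$", names(df), value = TRUE))
    if (any(df[[cn]] < 0, na.rm = TRUE))
      stop("negative times in column ", cn)
  for (cn in grep("_event$", names(df), value = TRUE))
    if (!all(df[[cn]] %in% c(0, 1, NA)))
      stop("event column ", cn, " must be 0/1")
  df
}
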