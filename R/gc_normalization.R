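#' LOESS GC-bias correction and percentage normalization
#'
#' Sequencing depth in shallow WGS depends smoothly on local GC content.
#' The correction fits a locally weighted regression of raw bin counts on
#' GC fraction over the usable bins, then rescales each bin by the ratio of
#' the median fitted value to its own fitted value.  The correction is
#' multiplicative because depth bias acts multiplicatively on counts.
#' Corrected counts are finally expressed as percentages of the usable-bin
#' total, the scale on which samples are compared to the reference panel.
#'
#' @name gc_normalization
NULL

#' Fit a LOESS model of count vs GC
#'
#' @param counts A \code{bin_counts} at stage \code{"raw"}.
#' @param gc A \code{gc_track} (or numeric vector of per-bin GC fractions).
#' @param bins The matching \code{bin_set}; only usable bins with
#'   non-missing GC enter the fit.
#' @param span LOESS span (default 0.3).
#' @param degree Local polynomial degree (default 1).
#' @param family LOESS family; \code{"symmetric"} (default) adds robustness
#'   iterations that downweight outlier bins.
#' @return A \code{gc_model}: list with the fitted \code{loess} object,
#'   per-bin fitted values (NA where not fit), \code{reference_level}
#'   (median fitted value) and the bins used.
#' @export
fit_gc_model <- function(counts, gc, bins, span = 0.3, degree = 1,
                         family = c("symmetric", "gaussian")) {
  stopifnot(inherits(counts, "bin_counts"), inherits(bins, "bin_set"))
  if (counts$stage != "raw")
    warning("fitting GC model on stage '", counts$stage, "' counts")
  family <- match.arg(family)
  gcv <- if (is.data.frame(gc)) gc$gc else as.numeric(gc)
  if (length(gcv) != nrow(bins)) stop("gc track length != number of bins")
  use <- bins$usable & !is.na(gcv) & !is.na(counts$counts)
  if (sum(use) < 50L)
    stop("need >= 50 usable bins with GC values to fit the GC model (got ",
         sum(use), ")")
  if (sum(counts$counts[use]) <= 0)
    stop("total count over usable bins must be positive")
  if (stats::sd(gcv[use]) == 0)
    stop("degenerate GC track (all values equal); skip GC correction")
  fit <- stats::loess(y ~ x,
                      data = data.frame(x = gcv[use], y = counts$counts[use]),
                      span = span, degree = degree, family = family,
                      surface = "direct")
  fitted_all <- rep(NA_real_, nrow(bins))
  fitted_all[use] <- stats::predict(fit, newdata = data.frame(x = gcv[use]))
  bad <- use & (is.na(fitted_all) | fitted_all <= 0)
  if (any(bad)) {
    message(sum(bad), " bin(s) with non-positive fitted depth demoted to unusable")
    fitted_all[bad] <- NA_real_
  }
  structure(list(span = span, degree = degree, family = family,
                 fitted = fitted_all,
                 reference_level = stats::median(fitted_all, na.rm = TRUE),
                 gc = gcv, used = use & !bad, loess = fit),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf("gc_model: loess span %.2f degree %d (%s), %d bins, reference level %.3f\n",
              x$span, x$degree, x$family, sum(x$used), x$reference_level))
  invisible(x)
}

#' Apply a fitted GC model to raw counts
#'
#' corrected_i = raw_i * reference_level / fitted_i over usable fitted bins;
#' bins outside the model (unusable, missing GC, non-positive fit) become
#' \code{NA}.
#'
#' @param counts A \code{bin_counts} at stage \code{"raw"} on the same bin
#'   set the model was fit on.
#' @param model A \code{gc_model}.
#' @param bins The matching \code{bin_set}.
#' @return A \code{bin_counts} at stage \code{"gc_corrected"}.
#' @export
correct_counts <- function(counts, model, bins) {
  stopifnot(inherits(counts, "bin_counts"), inherits(model, "gc_model"),
            inherits(bins, "bin_set"))
  if (length(model$fitted) != length(counts$counts))
    stop("GC model was fit on a different bin set")
  corrected <- rep(NA_real_, length(counts$counts))
  u <- model$used
  corrected[u] <- counts$counts[u] * model$reference_level / model$fitted[u]
  bin_counts(corrected, bins, sample_id = counts$sample_id,
             stage = "gc_corrected")
}

#' Convert corrected counts to normalized percentages
#'
#' pct_i = 100 * corrected_i / sum over usable bins of corrected, so the
#' usable bins sum to 100 exactly.  Scale-invariant: multiplying all
#' corrected counts by a constant leaves the percentages unchanged.
#'
#' @param counts A \code{bin_counts} at stage \code{"gc_corrected"} (raw
#'   counts are accepted when no GC correction is wanted).
#' @param bins The matching \code{bin_set}.
#' @return A \code{bin_counts} at stage \code{"normalized_percent"}.
#' @export
normalize_percent <- function(counts, bins) {
  stopifnot(inherits(counts, "bin_counts"), inherits(bins, "bin_set"))
  vals <- counts$counts
  vals[!bins$usable] <- NA_real_
  tot <- sum(vals[bins$usable], na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("total corrected count over usable bins must be positive")
  bin_counts(100 * vals / tot, bins, sample_id = counts$sample_id,
             stage = "normalized_percent")
}
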