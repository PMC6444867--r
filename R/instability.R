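#' Reference panel and genome instability scoring
#'
#' Healthy controls define, per usable bin, the mean and standard deviation
#' of the GC-corrected normalized read percentage.  A sample's per-bin
#' Z-score is its normalized percentage standardized against the panel.
#' Genome-wide instability is summarized by:
#' \itemize{
#'   \item the I-score: the sum of |Z| over bins with |Z| strictly greater
#'     than the threshold (default 2) — zero for a sample that matches the
#'     panel everywhere, and driven only by strongly deviating bins, which
#'     suppresses sequencing noise;
#'   \item the S-score: the sum of squared Z-scores over all scorable bins,
#'     a comparison statistic that keeps every bin's contribution.
#' }
#' Per-bin gain/loss calls use the same strict threshold.
#'
#' @name instability
NULL

#' Build a reference panel from healthy controls
#'
#' Per-bin mean and standard deviation (sample SD, n-1 denominator by
#' default) of normalized percentages across controls.  Bins where the
#' panel SD is zero cannot be standardized and are flagged unscorable.
#'
#' @param controls List of \code{bin_counts} at stage
#'   \code{"normalized_percent"}, all on the same bin set.
#' @param bins The shared \code{bin_set}.
#' @param sd_type \code{"sample"} (n-1, default) or \code{"population"} (n).
#' @return A \code{reference_panel}: list with \code{n_controls},
#'   \code{mean_pct}, \code{sd_pct}, \code{scorable} (per-bin logical) and
#'   the bin set.
#' @export
build_panel <- function(controls, bins, sd_type = c("sample", "population")) {
  stopifnot(inherits(bins, "bin_set"))
  sd_type <- match.arg(sd_type)
  if (length(controls) < 2L) stop("need at least 2 controls to build a panel")
  for (ctl in controls) {
    stopifnot(inherits(ctl, "bin_counts"))
    if (ctl$stage != "normalized_percent")
      stop("controls must be at stage 'normalized_percent'")
    if (length(ctl$counts) != nrow(bins))
      stop("control '", ctl$sample_id, "' is on a different bin set")
  }
  mat <- do.call(cbind, lapply(controls, `[[`, "counts"))
  n <- ncol(mat)
  mean_pct <- rowMeans(mat)
  sd_pct <- apply(mat, 1L, stats::sd)
  if (sd_type == "population") sd_pct <- sd_pct * sqrt((n - 1) / n)
  scorable <- bins$usable & !is.na(mean_pct) & !is.na(sd_pct) & sd_pct > 0
  n_zero <- sum(bins$usable & !is.na(sd_pct) & sd_pct == 0)
  if (n_zero > 0L)
    message(n_zero, " usable bin(s) with zero panel SD flagged unscorable")
  structure(list(n_controls = n, mean_pct = mean_pct, sd_pct = sd_pct,
                 scorable = scorable, bins = bins, sd_type = sd_type),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d controls, %d scorable of %d bins (%s SD)\n",
              x$n_controls, sum(x$scorable), nrow(x$bins), x$sd_type))
  invisible(x)
}

#' Per-bin Z-scores against a reference panel
#'
#' z_j = (pct_sample_j - mean_pct_j) / sd_pct_j on every scorable bin;
#' unscorable bins are returned as \code{NA}.
#'
#' @param sample A \code{bin_counts} at stage \code{"normalized_percent"}.
#' @param panel A \code{reference_panel} on the same bin set.
#' @return Numeric vector of per-bin Z-scores (NA on unscorable bins).
#' @export
zscores <- function(sample, panel) {
  stopifnot(inherits(sample, "bin_counts"), inherits(panel, "reference_panel"))
  if (sample$stage != "normalized_percent")
    stop("sample must be at stage 'normalized_percent'")
  if (length(sample$counts) != length(panel$mean_pct))
    stop("sample is on a different bin set than the panel")
  s <- panel$scorable
  if (any(s & is.na(sample$counts)))
    stop("sample has missing values on ",
         sum(s & is.na(sample$counts)), " scorable bin(s)")
  z <- rep(NA_real_, length(sample$counts))
  z[s] <- (sample$counts[s] - panel$mean_pct[s]) / panel$sd_pct[s]
  z
}

#' Genome instability I-score
#'
#' Sum of |z_j| over bins whose |z_j| is strictly greater than
#' \code{threshold}.  An empty selection gives 0, the expected value for a
#' normal sample that matches the panel.
#'
#' @param z Numeric per-bin Z-scores (NA entries are ignored).
#' @param threshold Call threshold (default 2); strict inequality.
#' @return Non-negative scalar.
#' @export
#' @examples
#' i_score(c(2.5, -3.0, 1.9, -1.5, 2.0))  # 5.5: only 2.5 and -3.0 qualify
i_score <- function(z, threshold = 2) {
  z <- z[!is.na(z)]
  sum(abs(z)[abs(z) > threshold])
}

#' S-score: sum of squared Z-scores
#'
#' Unlike the I-score, every scorable bin contributes, so baseline noise is
#' not suppressed.
#'
#' @param z Numeric per-bin Z-scores (NA entries are ignored).
#' @return Non-negative scalar.
#' @export
s_score <- function(z) sum(z[!is.na(z)]^2)

#' Per-bin gain/loss calls
#'
#' gain iff z > threshold, loss iff z < -threshold, neutral otherwise
#' (strict, consistent with the I-score); NA where z is NA.
#'
#' @param z Numeric per-bin Z-scores.
#' @param threshold Call threshold (default 2).
#' @return Character vector of \code{"gain"}, \code{"loss"},
#'   \code{"neutral"} or NA.
#' @export
call_cna <- function(z, threshold = 2) {
  out <- rep(NA_character_, length(z))
  ok <- !is.na(z)
  out[ok] <- ifelse(z[ok] > threshold, "gain",
                    ifelse(z[ok] < -threshold, "loss", "neutral"))
  out
}

#' Score a sample against the reference panel
#'
#' Convenience wrapper combining \code{\link{zscores}},
#' \code{\link{i_score}}, \code{\link{s_score}} and \code{\link{call_cna}}
#' into a profile object with print/summary/plot methods.
#'
#' @param sample A \code{bin_counts} at stage \code{"normalized_percent"}.
#' @param panel A \code{reference_panel} on the same bin set.
#' @param threshold Z threshold for the I-score and calls (default 2).
#' @return A \code{cna_profile}: list with \code{sample_id}, \code{z},
#'   \code{calls}, \code{i_score}, \code{s_score}, \code{threshold},
#'   \code{bins}.
#' @export
cna_profile <- function(sample, panel, threshold = 2) {
  z <- zscores(sample, panel)
  structure(list(sample_id = sample$sample_id, z = z,
                 calls = call_cna(z, threshold),
                 i_score = i_score(z, threshold),
                 s_score = s_score(z),
                 threshold = threshold, bins = panel$bins),
            class = "cna_profile")
}

#' @export
print.cna_profile <- function(x, ...) {
  cat(sprintf("cna_profile '%s': I-score %.1f, S-score %.1f (|Z| > %g)\n",
              x$sample_id, x$i_score, x$s_score, x$threshold))
  cat(sprintf("  %d gain, %d loss of %d scorable bins\n",
              sum(x$calls == "gain", na.rm = TRUE),
              sum(x$calls == "loss", na.rm = TRUE),
              sum(!is.na(x$z))))
  invisible(x)
}

#' Per-chromosome summary of a profile
#'
#' @param object A \code{cna_profile}.
#' @param ... Unused.
#' @return Data frame per chromosome: scorable bins, gain/loss counts,
#'   max |Z|.
#' @method summary cna_profile
#' @export
summary.cna_profile <- function(object, ...) {
  df <- data.frame(chrom = object$bins$chrom, z = object$z,
                   call = object$calls)
  agg <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    data.frame(chrom = d$chrom[1], scorable = sum(!is.na(d$z)),
               gain = sum(d$call == "gain", na.rm = TRUE),
               loss = sum(d$call == "loss", na.rm = TRUE),
               max_abs_z = if (all(is.na(d$z))) NA_real_ else
                 max(abs(d$z), na.rm = TRUE))
  }))
  agg <- agg[match(unique(object$bins$chrom), agg$chrom), ]
  rownames(agg) <- NULL
  agg
}

#' Linear genome plot of per-bin Z-scores
#'
#' One panel across the genome: Z-score against cumulative position with
#' chromosome boundaries, gains above the threshold in red, losses below in
#' blue (the usual linear rendering of a genome-wide instability profile).
#'
#' @param x A \code{cna_profile}.
#' @param ylim y-axis limits (default symmetric around the data).
#' @param ... Passed to \code{plot}.
#' @method plot cna_profile
#' @export
plot.cna_profile <- function(x, ylim = NULL, ...) {
  bins <- x$bins
  chroms <- unique(bins$chrom)
  chrom_len <- vapply(chroms, function(cc) max(bins$end[bins$chrom == cc]), 0)
  offs <- stats::setNames(cumsum(c(0, chrom_len[-length(chrom_len)])), chroms)
  pos <- offs[bins$chrom] + (bins$start + bins$end) / 2
  zz <- x$z
  if (is.null(ylim)) {
    m <- max(abs(zz), x$threshold * 1.5, na.rm = TRUE)
    ylim <- c(-m, m)
  }
  col <- ifelse(is.na(zz), NA,
                ifelse(zz > x$threshold, "red3",
                       ifelse(zz < -x$threshold, "blue3", "grey40")))
  plot(pos, zz, pch = 16, cex = 0.4, col = col, ylim = ylim,
       xlab = "genome position", ylab = "Z-score", xaxt = "n",
       main = sprintf("%s  (I-score %.0f)", x$sample_id, x$i_score), ...)
  graphics::abline(h = c(-x$threshold, 0, x$threshold),
                   lty = c(2, 1, 2), col = "grey60")
  graphics::abline(v = offs[-1], col = "grey85")
  graphics::axis(1, at = offs + chrom_len / 2, labels = sub("^chr", "", chroms),
                 tick = FALSE, cex.axis = 0.7)
  invisible(x)
}

#' Serialize a reference panel to TSV + JSON metadata
#'
#' @param panel A \code{reference_panel}.
#' @param path Output TSV path; metadata is written to \code{<path>.json}.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(chrom = panel$bins$chrom, start = panel$bins$start,
                   end = panel$bins$end, index = panel$bins$index,
                   mean_pct = panel$mean_pct, sd_pct = panel$sd_pct,
                   scorable = panel$scorable)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_controls = panel$n_controls, sd_type = panel$sd_type,
               build = attr(panel$bins, "build"),
               bin_size = attr(panel$bins, "bin_size"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized reference panel
#'
#' @param path TSV path written by \code{\link{write_panel}}.
#' @param bins The matching \code{bin_set}.
#' @return A \code{reference_panel}.
#' @export
read_panel <- function(path, bins) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) != nrow(bins)) stop("panel does not match bin set: ", path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(n_controls = meta$n_controls %||% NA_integer_,
                 mean_pct = df$mean_pct, sd_pct = df$sd_pct,
                 scorable = as.logical(df$scorable), bins = bins,
                 sd_type = meta$sd_type %||% "sample"),
            class = "reference_panel")
}

#' Export a profile for Circos-style plotting
#'
#' Writes (chrom, start, end, z) over scorable bins, the track format
#' consumed by Circos and similar genome-wheel renderers.
#'
#' @param profile A \code{cna_profile}.
#' @param path Output TSV path.
#' @export
write_circos_track <- function(profile, path) {
  keep <- !is.na(profile$z)
  df <- data.frame(chrom = profile$bins$chrom[keep],
                   start = profile$bins$start[keep],
                   end = profile$bins$end[keep],
                   z = profile$z[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a profile as TSV + JSON summary
#'
#' @param profile A \code{cna_profile}.
#' @param path Output TSV path (per-bin z and call); summary JSON goes to
#'   \code{<path>.json}.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(chrom = profile$bins$chrom, start = profile$bins$start,
                   end = profile$bins$end, index = profile$bins$index,
                   z = profile$z, call = profile$calls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sample_id = profile$sample_id,
                            i_score = profile$i_score,
                            s_score = profile$s_score,
                            threshold = profile$threshold),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
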