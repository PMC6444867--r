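#' Droplet digital PCR copy-number quantification
#'
#' In ddPCR the reaction is partitioned into ~20,000 droplets; template
#' molecules distribute across droplets approximately Poisson, so the mean
#' number of copies per droplet is recovered from the fraction of positive
#' droplets as lambda = -ln(1 - k/n).  The target copy number per diploid
#' genome is 2 * lambda_target / lambda_reference, with the reference locus
#' (here EIF2C1) assumed present at 2 copies.  Amplification is called when
#' the ratio strictly exceeds a cutoff derived from healthy controls
#' (mean + 3 SD).
#'
#' @name ddpcr
NULL

#' Poisson rate from droplet counts
#'
#' lambda = -ln(1 - k/n): mean template copies per droplet given k positive
#' droplets out of n accepted.
#'
#' @param k Positive droplets (0 <= k < n).
#' @param n Accepted droplets (> 0).
#' @return Copies per droplet (non-negative).
#' @export
#' @examples
#' poisson_rate(3000, 20000)  # -log(0.85)
poisson_rate <- function(k, n) {
  stopifnot(length(k) == length(n))
  if (any(n <= 0)) stop("accepted droplet count must be positive")
  if (any(k < 0)) stop("positive droplet count must be non-negative")
  if (any(k > n)) stop("positive droplets exceed accepted droplets")
  if (any(k == n))
    stop("all droplets positive: reaction saturated, rate undefined")
  -log(1 - k / n)
}

#' Droplet counts container
#'
#' @param sample_id Sample label.
#' @param k_target,n_target Positive / accepted droplets, target (VEGFA)
#'   channel.
#' @param k_ref,n_ref Positive / accepted droplets, reference (EIF2C1)
#'   channel.  Channels may have different accepted-droplet counts.
#' @return A \code{droplet_counts} object.
#' @export
droplet_counts <- function(sample_id, k_target, n_target, k_ref, n_ref) {
  stopifnot(n_target > 0, n_ref > 0, k_target >= 0, k_ref >= 0,
            k_target <= n_target, k_ref <= n_ref)
  structure(list(sample_id = sample_id, k_target = k_target,
                 n_target = n_target, k_ref = k_ref, n_ref = n_ref),
            class = "droplet_counts")
}

#' Target-to-reference copy-number ratio
#'
#' copy_number = 2 * lambda_target / lambda_ref, the target copies per
#' diploid genome under a diploid reference locus.
#'
#' @param d A \code{droplet_counts}.
#' @param reference_copies Copies of the reference locus per genome
#'   (default 2).
#' @return A \code{ddpcr_call}: list with \code{lambda_target},
#'   \code{lambda_ref}, \code{copy_number}; cutoff/amplified unset until
#'   \code{\link{amplification_call}}.
#' @export
vegfa_ratio <- function(d, reference_copies = 2) {
  stopifnot(inherits(d, "droplet_counts"))
  lt <- poisson_rate(d$k_target, d$n_target)
  lr <- poisson_rate(d$k_ref, d$n_ref)
  if (lr == 0) stop("no reference-channel signal (lambda_ref = 0)")
  structure(list(sample_id = d$sample_id, lambda_target = lt,
                 lambda_ref = lr,
                 copy_number = reference_copies * lt / lr,
                 cutoff = NA_real_, amplified = NA),
            class = "ddpcr_call")
}

#' @export
print.ddpcr_call <- function(x, ...) {
  cat(sprintf("ddpcr_call '%s': copy number %.3f (lambda %.4f / %.4f)",
              x$sample_id, x$copy_number, x$lambda_target, x$lambda_ref))
  if (!is.na(x$amplified))
    cat(sprintf("; %samplified (cutoff %.3f)",
                if (x$amplified) "" else "not ", x$cutoff))
  cat("\n")
  invisible(x)
}

#' Call amplification against a control-derived cutoff
#'
#' cutoff = mean(controls) + 3 * SD(controls) (sample SD); amplified iff
#' the copy number strictly exceeds the cutoff.  A fixed cutoff (e.g. a
#' previously established 2.60) may be supplied instead of control values.
#'
#' @param call A \code{ddpcr_call} (or a bare copy number).
#' @param control_values Copy numbers of >= 2 healthy controls, or NULL
#'   when \code{fixed_cutoff} is given.
#' @param fixed_cutoff Optional externally established cutoff.
#' @return The \code{ddpcr_call} with \code{cutoff} and \code{amplified}
#'   filled in.
#' @export
amplification_call <- function(call, control_values = NULL,
                               fixed_cutoff = NULL) {
  if (is.numeric(call))
    call <- structure(list(sample_id = "sample", lambda_target = NA_real_,
                           lambda_ref = NA_real_, copy_number = call,
                           cutoff = NA_real_, amplified = NA),
                      class = "ddpcr_call")
  stopifnot(inherits(call, "ddpcr_call"))
  if (!is.null(fixed_cutoff)) {
    cutoff <- fixed_cutoff
  } else {
    if (is.null(control_values) || length(control_values) < 2L)
      stop("need >= 2 control copy numbers or a fixed cutoff")
    cutoff <- mean(control_values) + 3 * stats::sd(control_values)
  }
  call$cutoff <- cutoff
  call$amplified <- call$copy_number > cutoff
  call
}

#' Read droplet counts from TSV
#'
#' Columns: sample_id, k_target, n_target, k_ref, n_ref.
#'
#' @param path TSV path.
#' @return List of \code{droplet_counts}.
#' @export
read_droplets_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "k_target", "n_target", "k_ref", "n_ref")
  if (!all(need %in% names(df)))
    stop("droplet TSV must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    droplet_counts(df$sample_id[i], df$k_target[i], df$n_target[i],
                   df$k_ref[i], df$n_ref[i]))
}
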