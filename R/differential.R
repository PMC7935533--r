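#' Paired tumor-minus-control differential expression
#'
#' Subtracts a patient's control (stroma) expression from the paired tumor
#' expression, gene by gene. Positive values indicate higher expression in
#' the tumor. Genes present in only one of the two samples are dropped and
#' counted. Both samples must be in the `uniprot` id space and share the same
#' normalization state.
#'
#' @param tumor,control [expression_vector()]s for the same patient.
#' @param patient_id patient label; defaults to the tumor sample id.
#' @param fit_range numeric length-2 `(lo, hi)`: the differential-expression
#'   interval inside which the Gaussian null is fitted. Default
#'   `c(-20000, 20000)`.
#' @param p one-tail cumulative probability for the critical value, in
#'   `[0.5, 1)`; default 0.975.
#' @return A `diff_profile` holding the named differential values, the fit
#'   parameters (populated by [fit_null()]) and the selection threshold, with
#'   attribute `n_dropped` counting unpaired genes.
#' @export
differential_expression <- function(tumor, control, patient_id = NULL,
                                    fit_range = c(-20000, 20000), p = 0.975) {
  stopifnot(inherits(tumor, "expression_vector"),
            inherits(control, "expression_vector"))
  if (tumor$id_space != "uniprot" || control$id_space != "uniprot")
    stop("tumor and control must be mapped to UniProtKB accessions first")
  if (tumor$norm_state != control$norm_state)
    stop(sprintf("normalization mismatch: tumor is '%s', control is '%s'",
                 tumor$norm_state, control$norm_state))
  if (is.null(patient_id)) patient_id <- tumor$sample_id
  shared <- intersect(names(tumor$values), names(control$values))
  n_dropped <- length(tumor$values) + length(control$values) - 2L * length(shared)
  diffs <- tumor$values[shared] - control$values[shared]
  out <- new_diff_profile(patient_id, diffs, fit_range, p)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Differential profile from precomputed values
#'
#' Wraps an existing named vector of tumor-minus-control differential values
#' in a `diff_profile`, e.g. when the subtraction was done elsewhere.
#'
#' @param diffs named numeric vector of differential values.
#' @inheritParams differential_expression
#' @return A `diff_profile`.
#' @export
diff_profile <- function(diffs, patient_id = "patient",
                         fit_range = c(-20000, 20000), p = 0.975) {
  new_diff_profile(patient_id, diffs, fit_range, p)
}

new_diff_profile <- function(patient_id, diffs, fit_range, p) {
  stopifnot(is.numeric(diffs), is.numeric(fit_range), length(fit_range) == 2L)
  if (fit_range[1] >= fit_range[2]) stop("fit_range must satisfy lo < hi")
  if (p < 0.5 || p >= 1) stop("p must be in [0.5, 1)")
  structure(list(patient_id = patient_id, diffs = diffs,
                 fit_mu = NA_real_, fit_sigma = NA_real_,
                 fit_range = as.numeric(fit_range), p = p,
                 critical_value = NA_real_),
            class = "diff_profile")
}

#' @export
print.diff_profile <- function(x, ...) {
  cat(sprintf("diff_profile '%s': %d genes", x$patient_id, length(x$diffs)))
  if (!is.na(x$fit_sigma))
    cat(sprintf("; null fit mu=%.4g sigma=%.4g", x$fit_mu, x$fit_sigma))
  if (!is.na(x$critical_value))
    cat(sprintf("; critical value %.4g (p=%.4g)", x$critical_value, x$p))
  cat("\n")
  invisible(x)
}

#' Fit the Gaussian null of a differential profile
#'
#' The bulk of paired differential values comes from genes that are not
#' differentially expressed and is modeled as Gaussian. The fit restricts to
#' values inside `fit_range` (default -20000..+20000) and matches moments:
#' the null mean is the sample mean and the null SD the population
#' (1/n) standard deviation of the in-range values — the maximum-likelihood
#' estimates for a Gaussian.
#'
#' @param profile a `diff_profile`.
#' @return The profile with `fit_mu` and `fit_sigma` populated.
#' @export
fit_null <- function(profile) {
  stopifnot(inherits(profile, "diff_profile"))
  x <- profile$diffs
  x <- x[x >= profile$fit_range[1] & x <= profile$fit_range[2]]
  if (length(x) < 30L)
    stop(sprintf("only %d differential values inside the fit range; at least 30 required",
                 length(x)))
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / length(x))
  if (sigma == 0) stop("degenerate fit: all in-range differential values are equal")
  profile$fit_mu <- mu
  profile$fit_sigma <- sigma
  profile
}

#' Critical value for up-regulation
#'
#' Returns the quantile of the fitted Gaussian null at the profile's one-tail
#' cumulative probability `p` (default 0.975): the threshold above which a
#' differential value is called up-regulated. If the quantile falls outside
#' the fit range the function errors, signalling that the range should be
#' widened (flattening normalizations can push the threshold far out).
#'
#' @param profile a `diff_profile` with the null fitted (see [fit_null()]).
#' @param p optional override of the profile's cumulative probability.
#' @return The profile with `critical_value` populated. Use
#'   `profile$critical_value` to read the number.
#' @export
critical_value <- function(profile, p = NULL) {
  stopifnot(inherits(profile, "diff_profile"))
  if (is.na(profile$fit_sigma)) stop("fit the null first (fit_null)")
  if (!is.null(p)) {
    if (p < 0.5 || p >= 1) stop("p must be in [0.5, 1)")
    profile$p <- p
  }
  cv <- stats::qnorm(profile$p, mean = profile$fit_mu, sd = profile$fit_sigma)
  if (cv < profile$fit_range[1] || cv > profile$fit_range[2])
    stop(sprintf(paste0("critical value %.6g is out of range [%g, %g]; ",
                        "widen fit_range to use this p"),
                 cv, profile$fit_range[1], profile$fit_range[2]))
  profile$critical_value <- cv
  profile
}

#' Select up-regulated genes
#'
#' Genes whose differential expression is strictly greater than the critical
#' value, returned in deterministic (accession-ascending) order.
#'
#' @param profile a `diff_profile` with `critical_value` populated.
#' @return Character vector of accessions.
#' @export
select_upregulated <- function(profile) {
  stopifnot(inherits(profile, "diff_profile"))
  if (is.na(profile$critical_value))
    stop("compute the critical value first (critical_value)")
  sort(names(profile$diffs)[profile$diffs > profile$critical_value])
}
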