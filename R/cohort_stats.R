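#' Sample summary for the Welch statistic
#'
#' Reduces a sample to the triple the Welch machinery consumes: the mean
#' \eqn{\bar x}, the sum of squared deviations from the mean
#' \eqn{SCE = \sum_i (x_i - \bar x)^2}, and the size n.
#'
#' @param x numeric vector, length >= 2.
#' @return A `sample_summary`: list with `mean`, `sce`, `n`.
#' @export
summarize_sample <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("at least 2 observations required")
  m <- mean(x)
  structure(list(mean = m, sce = sum((x - m)^2), n = length(x)),
            class = "sample_summary")
}

#' @rdname summarize_sample
#' @param mean,sce,n components of an already-computed summary.
#' @export
sample_summary <- function(mean, sce, n) {
  stopifnot(is.numeric(mean), is.numeric(sce), sce >= 0, n >= 2)
  structure(list(mean = mean, sce = sce, n = as.integer(n)),
            class = "sample_summary")
}

#' Welch two-sample statistic and degrees of freedom
#'
#' For two independent samples with unequal variances, `welch_statistic()`
#' computes
#' \deqn{u_{obs} = \frac{|\bar x_1 - \bar x_2|}
#'   {\sqrt{SCE_1/(n_1(n_1-1)) + SCE_2/(n_2(n_2-1))}}}
#' and `welch_df()` the Welch–Satterthwaite degrees of freedom
#' \deqn{k = \frac{(A + B)^2}{A^2/(n_1-1) + B^2/(n_2-1)},\quad
#'   A = \frac{SCE_1}{n_1(n_1-1)},\ B = \frac{SCE_2}{n_2(n_2-1)},}
#' which satisfies \eqn{n_1 - 1 < k < n_1 + n_2 - 2} for unequal variances.
#' The observed statistic is compared to Student-t quantiles at k degrees of
#' freedom (see [t_quantile()]); this is how cohort-average subnetwork
#' entropies of two cancer types are compared.
#'
#' @param s1,s2 `sample_summary` objects (see [summarize_sample()]).
#' @return `welch_statistic()`: the non-negative statistic; `welch_df()`: k.
#' @export
welch_statistic <- function(s1, s2) {
  ab <- welch_terms(s1, s2)
  abs(s1$mean - s2$mean) / sqrt(ab[1] + ab[2])
}

#' @rdname welch_statistic
#' @export
welch_df <- function(s1, s2) {
  ab <- welch_terms(s1, s2)
  (ab[1] + ab[2])^2 / (ab[1]^2 / (s1$n - 1) + ab[2]^2 / (s2$n - 1))
}

welch_terms <- function(s1, s2) {
  stopifnot(inherits(s1, "sample_summary"), inherits(s2, "sample_summary"))
  if (s1$sce == 0 && s2$sce == 0)
    stop("degenerate input: both samples have zero variance")
  c(s1$sce / (s1$n * (s1$n - 1)), s2$sce / (s2$n * (s2$n - 1)))
}

#' Student-t quantile
#'
#' Inverse CDF of Student's t distribution, used as the theoretical value
#' against which the Welch statistic is compared (e.g. 2.045 at p = 0.975 and
#' 3.396 at p = 0.999 for 29 degrees of freedom).
#'
#' @param p cumulative probability in (0, 1).
#' @param df degrees of freedom (> 0, not necessarily integer).
#' @return The quantile.
#' @export
t_quantile <- function(p, df) {
  stopifnot(p > 0, p < 1, df > 0)
  stats::qt(p, df)
}

#' Entropy versus 5-year overall survival regression
#'
#' Ordinary least squares of per-cancer-type mean subnetwork entropy (bits)
#' on 5-year overall survival (percent), plus the Pearson correlation. A
#' negative correlation — more complex up-regulated subnetworks in cancers
#' with worse survival — is the external criterion used to validate
#' normalization choices.
#'
#' @param table data frame with columns `cancer_type`, `entropy` (bits) and
#'   `five_year_os` (percent, 0-100); at least 3 rows.
#' @return List with `pearson_r`, `slope`, `intercept`, `r_squared` and `n`
#'   (entropy = slope * OS + intercept).
#' @export
entropy_os_regression <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("entropy", "five_year_os") %in% names(table)))
  if (nrow(table) < 3L) stop("at least 3 cancer types required for regression")
  os <- table$five_year_os
  h <- table$entropy
  if (any(os < 0 | os > 100)) stop("five_year_os must be a percentage in [0, 100]")
  if (stats::sd(os) == 0) stop("degenerate input: constant overall survival")
  fit <- stats::lm(h ~ os)
  r <- stats::cor(h, os)
  list(pearson_r = r,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r^2,
       n = nrow(table))
}
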