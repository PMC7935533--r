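#' Expression-count normalization
#'
#' Five transforms of per-sample read counts. With \eqn{RC_g} the count of
#' reads mapped to gene \eqn{g}, \eqn{RC_{pc}} the total count over all genes
#' in the sample, and \eqn{L_g} the coding-sequence length in base pairs:
#'
#' \describe{
#'   \item{`rpkm()`}{\eqn{RC_g \cdot 10^9 / (RC_{pc} \cdot L_g)}}
#'   \item{`rpkm_upper()`}{\eqn{RC_g \cdot 10^9 / (L_g \cdot (RC_{pc} - \delta
#'     RC_{pc}))}; the tuning factor \eqn{\delta \in [0,1)} shrinks the
#'     library-size denominator. At \eqn{\delta = 0} this is RPKM; at
#'     \eqn{\delta = 0.25} it emulates upper-quartile scaling.}
#'   \item{`upper_quartile()`}{\eqn{RC_g \cdot 10^9 / (RC_{g75} \cdot L_g)}
#'     where \eqn{RC_{g75}} is the 75th percentile (linear interpolation) of
#'     the sample's nonzero counts.}
#'   \item{`lognorm()`}{\eqn{C x (\log_b(\log_b(x+1)) + 1)} applied to each
#'     already-normalized value \eqn{x}, flattening the power-law tail the way
#'     variance-stabilized public expression matrices are flattened. By
#'     convention \eqn{f(0)=0}; for very small positive \eqn{x} the formula is
#'     negative and is applied as-is.}
#'   \item{`log2norm()`}{\eqn{x \log_b(x+1)}, a milder flattening;
#'     \eqn{f(0)=0}.}
#' }
#'
#' @param counts an [expression_vector()] of raw counts.
#' @param lengths named integer vector of coding-sequence lengths (bp),
#'   covering every gene in `counts` (see [read_gene_lengths()]).
#' @param delta tuning factor \eqn{\delta} in `[0, 1)`; default 0.05.
#' @param .state internal: `norm_state` tag of the result.
#' @return An [expression_vector()] with the corresponding `norm_state`.
#' @export
rpkm <- function(counts, lengths) {
  rpkm_upper(counts, lengths, delta = 0, .state = "rpkm")
}

#' @rdname rpkm
#' @export
rpkm_upper <- function(counts, lengths, delta = 0.05, .state = "rpkm_upper") {
  stopifnot(inherits(counts, "expression_vector"),
            counts$norm_state == "raw_counts")
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  L <- gene_lengths_for(counts, lengths)
  rc <- counts$values
  rc_pc <- sum(rc)
  if (rc_pc <= 0) stop("degenerate input: all counts are zero")
  vals <- rc * 1e9 / (L * (rc_pc - delta * rc_pc))
  expression_vector(vals, counts$sample_id, counts$id_space, .state)
}

#' @rdname rpkm
#' @export
upper_quartile <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_vector"),
            counts$norm_state == "raw_counts")
  L <- gene_lengths_for(counts, lengths)
  rc <- counts$values
  nz <- rc[rc > 0]
  if (length(nz) == 0L) stop("degenerate input: all counts are zero")
  rc_g75 <- unname(stats::quantile(nz, 0.75, type = 7))
  if (rc_g75 <= 0) stop("degenerate input: zero upper-quartile count")
  vals <- rc * 1e9 / (rc_g75 * L)
  expression_vector(vals, counts$sample_id, counts$id_space, "uq")
}

#' @rdname rpkm
#' @param values an [expression_vector()] of already-normalized values
#'   (typically `rpkm_upper` output).
#' @param C multiplicative constant of the double-log transform; default 20.
#' @param b logarithm base (> 1); default 1.1 for `lognorm()`, 2 for
#'   `log2norm()`.
#' @export
lognorm <- function(values, C = 20, b = 1.1) {
  stopifnot(inherits(values, "expression_vector"))
  if (b <= 1) stop("log base must be > 1")
  if (any(values$values < 0)) stop("lognorm input values must be >= 0")
  x <- values$values
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- C * x[pos] * (log(log(x[pos] + 1, b), b) + 1)
  names(out) <- names(x)
  expression_vector(out, values$sample_id, values$id_space, "lognorm")
}

#' @rdname rpkm
#' @export
log2norm <- function(values, b = 2) {
  stopifnot(inherits(values, "expression_vector"))
  if (b <= 1) stop("log base must be > 1")
  if (any(values$values < 0)) stop("log2norm input values must be >= 0")
  x <- values$values
  out <- x * log(x + 1, b)
  expression_vector(out, values$sample_id, values$id_space, "log2")
}

#' Normalize raw counts by a named method
#'
#' Dispatch helper used by the pipeline and the command-line tool.
#' `"chain"` runs `rpkm_upper` followed by `log2norm`, the default
#' normalization of the end-to-end pipeline.
#'
#' @param counts an [expression_vector()] of raw counts.
#' @param lengths named integer vector of coding-sequence lengths (bp).
#' @param method one of `"rpkm"`, `"rpkm-upper"`, `"uq"`, `"lognorm"`,
#'   `"log2"`, `"chain"` (`"lognorm"` and `"log2"` run `rpkm_upper` first,
#'   since those transforms act on normalized values).
#' @param delta,C,b_lognorm,b_log2 transform constants (see [rpkm()]).
#' @return An [expression_vector()].
#' @export
normalize_counts <- function(counts, lengths,
                             method = c("chain", "rpkm", "rpkm-upper", "uq",
                                        "lognorm", "log2"),
                             delta = 0.05, C = 20, b_lognorm = 1.1, b_log2 = 2) {
  method <- match.arg(method)
  switch(method,
    "rpkm" = rpkm(counts, lengths),
    "rpkm-upper" = rpkm_upper(counts, lengths, delta),
    "uq" = upper_quartile(counts, lengths),
    "lognorm" = lognorm(rpkm_upper(counts, lengths, delta), C, b_lognorm),
    "log2" = ,
    "chain" = log2norm(rpkm_upper(counts, lengths, delta), b_log2))
}

gene_lengths_for <- function(counts, lengths) {
  L <- lengths[names(counts$values)]
  missing <- names(counts$values)[is.na(L)]
  if (length(missing) > 0L)
    stop(sprintf("no coding-sequence length for: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  if (any(L <= 0)) stop("coding-sequence lengths must be positive")
  as.numeric(L)
}
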