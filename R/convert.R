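# Cohen's d <-> Hedges' g harmonization.
#
# Hedges' g is Cohen's d shrunk by the small-sample bias-correction factor
# J = 1 - 3 / (4(n1 + n2) - 9), which depends on the sample sizes only
# through their sum and approaches 1 as the total grows.

#' Small-sample correction factor J
#'
#' @param n_total total sample size (n1 + n2); must be >= 3 so that the
#'   denominator 4 n_total - 9 is positive.
#' @return J = 1 - 3/(4 n_total - 9), a value in (0, 1].
#' @export
hedges_correction <- function(n_total) {
  if (any(!is.finite(n_total)) || any(n_total < 3))
    stop("total sample size must be >= 3", call. = FALSE)
  1 - 3 / (4 * n_total - 9)
}

.n_total <- function(n1, n2) {
  # A single argument is read as the total: the correction depends only on
  # the sum, and some sources report just one overall N.
  if (is.null(n2) || all(is.na(n2))) n1 else n1 + n2
}

#' Convert Cohen's d to Hedges' g
#'
#' g = d * (1 - 3/(4(n1 + n2) - 9)). Sign is preserved and |g| < |d| for
#' any finite sample size when d is nonzero.
#'
#' @param d signed standardized mean difference on the d scale.
#' @param n1,n2 group sample sizes. If `n2` is omitted, `n1` is taken as the
#'   total sample size.
#' @return the value on the Hedges' g scale.
#' @examples
#' d_to_g(0.5, 10, 10)   # 0.5 * (1 - 3/71)
#' @export
d_to_g <- function(d, n1, n2 = NULL) {
  d * hedges_correction(.n_total(n1, n2))
}

#' Convert Hedges' g to Cohen's d
#'
#' Exact algebraic inverse of [d_to_g()]: d = g / (1 - 3/(4(n1 + n2) - 9)).
#'
#' @inheritParams d_to_g
#' @param g signed standardized mean difference on the g scale.
#' @return the value on the Cohen's d scale.
#' @export
g_to_d <- function(g, n1, n2 = NULL) {
  g / hedges_correction(.n_total(n1, n2))
}

#' Harmonize an effects table to the Cohen's d scale
#'
#' Records reported as Hedges' g with known sample sizes are converted to
#' Cohen's d through the inverse correction and relabelled; their CI bounds
#' are rescaled by the same multiplicative factor as the point estimate
#' (the correction is a deterministic rescaling). Hedges' g records lacking
#' sample sizes are passed through unchanged and flagged `"unconverted_g"` in
#' a `conversion_flag` column -- they stay in the pooled distribution, as is
#' conventional when no conversion is possible. Cohen's d records pass
#' through untouched.
#'
#' @param records an `effects_df`.
#' @return the same table on the d scale, with a `conversion_flag` column
#'   (`NA`, `"converted_from_g"` or `"unconverted_g"`).
#' @export
harmonize_to_d <- function(records) {
  records <- validate_effects(as.data.frame(records))
  flag <- rep(NA_character_, nrow(records))
  is_g <- records$es_metric == "hedges_g"
  has_n <- !is.na(records$n_treatment) & !is.na(records$n_control)
  conv <- is_g & has_n
  if (any(conv)) {
    J <- hedges_correction(records$n_treatment[conv] +
                             records$n_control[conv])
    records$es_value[conv] <- records$es_value[conv] / J
    records$ci_lower[conv] <- records$ci_lower[conv] / J
    records$ci_upper[conv] <- records$ci_upper[conv] / J
    records$es_metric[conv] <- "cohens_d"
    flag[conv] <- "converted_from_g"
  }
  flag[is_g & !has_n] <- "unconverted_g"
  records$conversion_flag <- flag
  validate_effects(records)
}

#' Standard error from a symmetric confidence interval
#'
#' Assumes a normal-theory interval: se = (upper - lower) / (2 z), with z
#' the standard-normal quantile at (1 + level)/2 (1.959964 at 95%). When a
#' point `estimate` is supplied and sits away from the interval midpoint,
#' the interval is flagged as asymmetric with a warning and half the full
#' width is still used.
#'
#' @param ci_lower,ci_upper interval bounds (vectorized).
#' @param level coverage probability, default 0.95.
#' @param estimate optional point estimate used to detect asymmetry.
#' @return non-negative standard error(s).
#' @examples
#' se_from_ci(0.1, 0.9)   # 0.204085
#' @export
se_from_ci <- function(ci_lower, ci_upper, level = 0.95, estimate = NULL) {
  if (any(!is.finite(level)) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  if (any(ci_upper < ci_lower, na.rm = TRUE))
    stop("inverted interval: ci_upper < ci_lower", call. = FALSE)
  width <- ci_upper - ci_lower
  if (!is.null(estimate)) {
    mid <- (ci_upper + ci_lower) / 2
    asym <- abs(mid - estimate) > 0.01 * pmax(width, .Machine$double.eps)
    if (any(asym, na.rm = TRUE))
      warning(sum(asym, na.rm = TRUE),
              " asymmetric interval(s): using half the full width",
              call. = FALSE)
  }
  width / (2 * stats::qnorm((1 + level) / 2))
}
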