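# Exact a priori power for t tests via the noncentral t distribution.
#
# Two-sample: df = n1 + n2 - 2, noncentrality lambda = d * sqrt(n1 n2 / (n1 + n2)).
# Paired:     df = n - 1,       lambda = d * sqrt(n), d on the difference scale.
# Two-tailed power includes the wrong-direction rejection tail, matching
# standard power software.

.power_nct <- function(ncp, df, alpha, tails) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (tails == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp = ncp) + 1 - stats::pt(tc, df, ncp = ncp)
  } else {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
  }
}

#' Power of an independent-samples t test
#'
#' @param d non-negative standardized mean difference.
#' @param n1,n2 group sample sizes (each >= 2); `n2` defaults to `n1`.
#' @param alpha type-I error rate, default 0.05.
#' @param tails `"two"` (default) or `"one"`.
#' @return rejection probability under the alternative.
#' @examples
#' power_two_sample(1.21, 21, 20)   # 0.965
#' @export
power_two_sample <- function(d, n1, n2 = n1, alpha = 0.05,
                             tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  if (any(n1 < 2) || any(n2 < 2))
    stop("group sizes must be >= 2", call. = FALSE)
  .power_nct(d * sqrt(n1 * n2 / (n1 + n2)), n1 + n2 - 2, alpha, tails)
}

#' Power of a paired-samples t test
#'
#' @param d non-negative standardized mean difference on the
#'   paired-difference scale.
#' @param n_pairs number of pairs (>= 2).
#' @inheritParams power_two_sample
#' @return rejection probability under the alternative.
#' @export
power_paired <- function(d, n_pairs, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  if (any(n_pairs < 2)) stop("n_pairs must be >= 2", call. = FALSE)
  .power_nct(d * sqrt(n_pairs), n_pairs - 1, alpha, tails)
}

#' Minimal sample size reaching a target power
#'
#' Returns the smallest integer n (number of pairs, or per-group size with
#' n1 = n2) whose exact noncentral-t power meets the target, found by
#' geometric bracketing followed by integer bisection on the monotone
#' power function. The returned result always satisfies
#' `power(n_required) >= target_power` and `power(n_required - 1) < target_power`.
#'
#' @param design `"paired"` or `"two_sample"`.
#' @param d positive standardized mean difference.
#' @param target_power requested power in (0, 1), default 0.80.
#' @inheritParams power_two_sample
#' @return object of class `sample_size_result`: list with `n_required`,
#'   `achieved_power`, `target_power`, `design`, `d`, `alpha`, `tails`.
#' @examples
#' required_n("two_sample", 1.21)   # 12 per group
#' @export
required_n <- function(design = c("paired", "two_sample"), d,
                       target_power = 0.80, alpha = 0.05,
                       tails = c("two", "one")) {
  design <- match.arg(design)
  tails <- match.arg(tails)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must be in (0, 1)", call. = FALSE)
  if (d <= 0)
    stop("d must be positive: power cannot reach the target under the null",
         call. = FALSE)
  pw <- function(n) switch(design,
    paired = power_paired(d, n, alpha, tails),
    two_sample = power_two_sample(d, n, n, alpha, tails))
  lo <- 2L
  hi <- 2L
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e7) stop("required sample size exceeds 1e7", call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  n_req <- if (pw(lo) >= target_power) lo else hi
  res <- list(n_required = n_req, achieved_power = pw(n_req),
              target_power = target_power, design = design, d = d,
              alpha = alpha, tails = tails)
  class(res) <- "sample_size_result"
  res
}

#' @export
print.sample_size_result <- function(x, ...) {
  unit <- if (x$design == "paired") "pairs" else "per group"
  cat(sprintf(
    "Required n (%s, d = %g, %s-tailed, alpha = %g): %d %s (power %.3f >= %.2f)\n",
    x$design, x$d, x$tails, x$alpha, x$n_required, unit,
    x$achieved_power, x$target_power))
  invisible(x)
}

#' Sample-size requirements over a grid of effects and power levels
#'
#' @param design `"paired"` or `"two_sample"`.
#' @param d_grid positive effect sizes.
#' @param power_levels target powers, default 0.7 / 0.8 / 0.9.
#' @inheritParams power_two_sample
#' @return data.frame sorted by (power_level, d): columns `power_level`,
#'   `d`, `n_required`, `achieved_power`.
#' @export
power_curve <- function(design = c("paired", "two_sample"), d_grid,
                        power_levels = c(0.7, 0.8, 0.9), alpha = 0.05,
                        tails = c("two", "one")) {
  design <- match.arg(design)
  tails <- match.arg(tails)
  grid <- expand.grid(d = sort(d_grid), power_level = sort(power_levels))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- required_n(design, grid$d[i], grid$power_level[i], alpha, tails)
    data.frame(power_level = grid$power_level[i], d = grid$d[i],
               n_required = r$n_required, achieved_power = r$achieved_power)
  })
  out <- do.call(rbind, rows)
  out[order(out$power_level, out$d), , drop = FALSE]
}
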