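# Correlates of effect magnitude: bivariate OLS with cluster-aware
# inference. Effects extracted from the same meta-analysis are correlated,
# so plain OLS standard errors are too small; the sandwich variance sums
# score contributions within clusters and applies the small-sample factor
# c = [G/(G-1)] * [(N-1)/(N-k)] (the Stata vce(cluster) convention), with
# a t reference on G-1 degrees of freedom. A clustered bootstrap
# (resampling whole clusters with replacement) gives a nonparametric
# percentile interval for the slope.

#' Bivariate OLS with cluster-robust standard errors
#'
#' Fits `y ~ x` by ordinary least squares and computes the cluster-robust
#' (CR1) sandwich variance via [sandwich::vcovCL()] with the Stata
#' small-sample factor. The confidence interval and p-value use a t
#' reference with G - 1 degrees of freedom (G = number of clusters) by
#' default; a normal reference is available.
#'
#' @param y response (effect magnitudes).
#' @param x covariate (e.g. publication year, log10 total sample size).
#' @param cluster_ids cluster labels (parent meta-analysis per observation).
#' @param conf_level interval coverage, default 0.95.
#' @param df_method `"t_cluster"` (t on G-1 df, default) or `"normal"`.
#' @return object of class `regression_fit`: list with `beta`, `intercept`,
#'   `se_adj`, `ci_lower`, `ci_upper`, `p_value`, `n_obs`, `n_clusters`,
#'   `vcov`, `df_method`, `conf_level`.
#' @export
fit_cluster_ols <- function(y, x, cluster_ids, conf_level = 0.95,
                            df_method = c("t_cluster", "normal")) {
  df_method <- match.arg(df_method)
  ok <- stats::complete.cases(y, x, cluster_ids)
  y <- y[ok]; x <- x[ok]; cluster_ids <- as.character(cluster_ids)[ok]
  n <- length(y)
  if (length(x) != n || length(cluster_ids) != n)
    stop("y, x and cluster_ids must have equal length", call. = FALSE)
  if (n < 3) stop("at least 3 observations are required", call. = FALSE)
  G <- length(unique(cluster_ids))
  if (G < 2) stop("at least 2 clusters are required", call. = FALSE)
  if (stats::var(x) == 0)
    stop("constant covariate: slope is not identified", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # degenerate zero-residual designs are legitimate here (se_adj = 0)
  V <- withCallingHandlers(
    sandwich::vcovCL(fit, cluster = cluster_ids, type = "HC1",
                     cadjust = TRUE),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[2])
  se <- sqrt(V[2, 2])
  q <- if (df_method == "t_cluster")
    stats::qt(1 - (1 - conf_level) / 2, df = G - 1)
  else stats::qnorm(1 - (1 - conf_level) / 2)
  tval <- if (se > 0) beta / se else ifelse(beta == 0, 0, Inf * sign(beta))
  p <- if (df_method == "t_cluster") 2 * stats::pt(-abs(tval), df = G - 1)
  else 2 * stats::pnorm(-abs(tval))
  res <- list(beta = beta, intercept = unname(stats::coef(fit)[1]),
              se_adj = se, ci_lower = beta - q * se, ci_upper = beta + q * se,
              p_value = p, n_obs = n, n_clusters = G, vcov = V,
              df_method = df_method, conf_level = conf_level)
  class(res) <- "regression_fit"
  res
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Cluster-robust OLS (N = %d, G = %d clusters, %s reference)\n",
    x$n_obs, x$n_clusters,
    if (x$df_method == "t_cluster") sprintf("t[%d]", x$n_clusters - 1)
    else "normal"))
  cat(sprintf("  beta = %.4f  SE_adj = %.4f  %g%% CI (%.4f, %.4f)  p = %.4g\n",
              x$beta, x$se_adj, 100 * x$conf_level,
              x$ci_lower, x$ci_upper, x$p_value))
  invisible(x)
}

#' Clustered bootstrap percentile interval for the slope
#'
#' Resamples G clusters with replacement (keeping every row of each drawn
#' cluster), refits the OLS slope per replicate, and returns the percentile
#' interval over replicate slopes. Replicates whose resampled design is
#' degenerate (essentially constant covariate) are redrawn, up to a cap;
#' the redraw count is reported. Deterministic for a fixed seed.
#'
#' @inheritParams fit_cluster_ols
#' @param n_replicates bootstrap replicates, default 10000.
#' @param seed integer seed (required part of the resampling protocol).
#' @param ci_level interval coverage, default 0.95.
#' @param max_redraws cap on degenerate-replicate redraws, default 1000.
#' @return list with `ci_lower`, `ci_upper`, `replicates` (slope draws),
#'   `n_replicates`, `n_redraws`, `seed`.
#' @export
cluster_bootstrap_ci <- function(y, x, cluster_ids, n_replicates = 10000,
                                 seed = 1, ci_level = 0.95,
                                 max_redraws = 1000) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  ok <- stats::complete.cases(y, x, cluster_ids)
  y <- y[ok]; x <- x[ok]; cluster_ids <- as.character(cluster_ids)[ok]
  idx_by_cluster <- split(seq_along(y), cluster_ids)
  G <- length(idx_by_cluster)
  if (G < 2) stop("at least 2 clusters are required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  slopes <- numeric(n_replicates)
  n_redraws <- 0L
  for (b in seq_len(n_replicates)) {
    repeat {
      drawn <- sample.int(G, G, replace = TRUE)
      idx <- unlist(idx_by_cluster[drawn], use.names = FALSE)
      xb <- x[idx]
      vx <- stats::var(xb)
      if (is.finite(vx) && vx > .Machine$double.eps) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop("too many degenerate bootstrap replicates (constant covariate)",
             call. = FALSE)
    }
    slopes[b] <- stats::cov(xb, y[idx]) / vx
  }
  a <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(slopes, probs = c(a, 1 - a), type = 7))
  list(ci_lower = ci[1], ci_upper = ci[2], replicates = slopes,
       n_replicates = n_replicates, n_redraws = n_redraws, seed = seed)
}

#' LOESS trend curve on a grid
#'
#' Local weighted polynomial regression (tricube weights over the
#' span-nearest neighbours) via [stats::loess()] with exact (direct)
#' surface evaluation, returned as a table for re-plotting. Evaluation is
#' restricted to the observed covariate range: no extrapolation.
#'
#' @param x,y observations.
#' @param span smoothing parameter f in (0, 1], default 0.75.
#' @param degree local polynomial degree, default 2.
#' @param grid evaluation points; default 101 equally spaced points over
#'   the range of `x`.
#' @return data.frame with columns `x` (grid) and `fitted`.
#' @export
loess_curve <- function(x, y, span = 0.75, degree = 2, grid = NULL) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < max(degree + 2, ceiling(span * n)))
    stop("too few points for the requested span/degree", call. = FALSE)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 101)
  if (any(grid < min(x)) || any(grid > max(x)))
    stop("grid requests extrapolation beyond the observed x range",
         call. = FALSE)
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  data.frame(x = grid,
             fitted = stats::predict(fit, newdata = data.frame(x = grid)))
}
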