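# Statistical power of meta-analytic summary effects.
#
# Each meta-analysis reports a summary effect with a standard error (given
# directly, or derived from its 95% CI). Its power to detect an assumed
# true effect delta under a two-tailed z test is
#   1 - Phi(z_{1-a/2} - delta/se) + Phi(-z_{1-a/2} - delta/se),
# profiled over a grid of plausible true effects (default delta = 0.1 ... 1.0)
# and at the observed summary effect's magnitude.

#' Read a meta-analysis summary table from CSV
#'
#' Required columns: `meta_id`, `summary_es`, and either `se` or both
#' `ci_lower` and `ci_upper` (95% bounds) from which the standard error is
#' derived via [se_from_ci()].
#'
#' @param path CSV path (UTF-8, header row, empty cell = missing).
#' @return data.frame with columns `meta_id`, `summary_es`, `ci_lower`,
#'   `ci_upper`, `se`.
#' @export
read_meta_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", na.strings = c("", "NA"))
  need <- c("meta_id", "summary_es")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("ci_lower", "ci_upper", "se"))
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  derive <- is.na(raw$se)
  if (any(derive)) {
    has_ci <- !is.na(raw$ci_lower) & !is.na(raw$ci_upper)
    bad <- which(derive & !has_ci)
    if (length(bad) > 0)
      stop(sprintf("row %d: no standard error and no CI to derive it from",
                   bad[1]), call. = FALSE)
    raw$se[derive] <- se_from_ci(raw$ci_lower[derive], raw$ci_upper[derive])
  }
  if (any(raw$se <= 0))
    stop("standard errors must be positive", call. = FALSE)
  raw[c("meta_id", "summary_es", "ci_lower", "ci_upper", "se")]
}

#' Two-tailed z-test power at an assumed true effect
#'
#' @param delta non-negative assumed true effect magnitude.
#' @param se positive standard error of the summary effect (vectorized).
#' @param alpha type-I error rate, default 0.05.
#' @return rejection probability; equals `alpha` at `delta = 0` and
#'   approaches 1 as `se` shrinks.
#' @examples
#' meta_power_at(0.5, 0.2)   # 0.7054
#' @export
meta_power_at <- function(delta, se, alpha = 0.05) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(zc - delta / se) + stats::pnorm(-zc - delta / se)
}

#' Power profile of one meta-analysis across a delta grid
#'
#' @param meta one-row data.frame (or list) with `meta_id`, `summary_es`
#'   and `se` (or `ci_lower`/`ci_upper` from which se is derived).
#' @param delta_grid ordered grid of assumed true effect magnitudes,
#'   default 0.1 to 1.0 in steps of 0.1.
#' @param alpha type-I error rate, default 0.05.
#' @return object of class `meta_power_profile`: list with `meta_id`,
#'   `delta_grid`, `power_at_delta` and `power_at_observed` (power at the
#'   absolute observed summary effect).
#' @export
meta_power_profile <- function(meta, delta_grid = seq(0.1, 1.0, by = 0.1),
                               alpha = 0.05) {
  se <- meta$se
  if (is.null(se) || length(se) == 0 || is.na(se)) {
    if (!is.null(meta$ci_lower) && !is.null(meta$ci_upper) &&
        !is.na(meta$ci_lower) && !is.na(meta$ci_upper))
      se <- se_from_ci(meta$ci_lower, meta$ci_upper)
    else stop("no standard error and no CI to derive it from", call. = FALSE)
  }
  res <- list(meta_id = as.character(meta$meta_id),
              delta_grid = delta_grid,
              power_at_delta = meta_power_at(delta_grid, se, alpha),
              power_at_observed = meta_power_at(abs(meta$summary_es), se,
                                                alpha),
              se = se, summary_es = meta$summary_es, alpha = alpha)
  class(res) <- "meta_power_profile"
  res
}

#' @export
print.meta_power_profile <- function(x, ...) {
  cat(sprintf("Power profile for meta-analysis %s (se = %.3f)\n",
              x$meta_id, x$se))
  cat(sprintf("  power at observed |es| = %.2f: %.3f\n",
              abs(x$summary_es), x$power_at_observed))
  cat("  delta: ", paste(sprintf("%.1f", x$delta_grid), collapse = " "), "\n")
  cat("  power: ", paste(sprintf("%.3f", x$power_at_delta), collapse = " "),
      "\n")
  invisible(x)
}

#' Power profiles for a whole meta-summary table
#'
#' @param metas data.frame as returned by [read_meta_summaries()] or
#'   [generate_meta_dataset()].
#' @inheritParams meta_power_profile
#' @return list of `meta_power_profile` objects.
#' @export
meta_power_profiles <- function(metas, delta_grid = seq(0.1, 1.0, by = 0.1),
                                alpha = 0.05) {
  lapply(seq_len(nrow(metas)), function(i)
    meta_power_profile(metas[i, , drop = FALSE], delta_grid, alpha))
}

#' Median (and min/mean/max) power across meta-analyses
#'
#' Element-wise summaries across profiles at every grid point, plus the
#' same summaries of the power at each meta-analysis's observed effect.
#' Even profile counts average the two central order statistics (the
#' standard median).
#'
#' @param profiles non-empty list of `meta_power_profile` objects sharing
#'   one delta grid.
#' @return list with `delta_grid`, `median`, `mean`, `min`, `max` (vectors
#'   along the grid) and `at_observed` (named summaries of observed-effect
#'   power).
#' @export
median_power <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles supplied", call. = FALSE)
  grid <- profiles[[1]]$delta_grid
  mat <- vapply(profiles, function(p) {
    if (!isTRUE(all.equal(p$delta_grid, grid)))
      stop("profiles use different delta grids", call. = FALSE)
    p$power_at_delta
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  obs <- vapply(profiles, `[[`, numeric(1), "power_at_observed")
  list(delta_grid = grid,
       median = apply(mat, 1, stats::median),
       mean = rowMeans(mat),
       min = apply(mat, 1, min),
       max = apply(mat, 1, max),
       at_observed = c(median = stats::median(obs), mean = mean(obs),
                       min = min(obs), max = max(obs)))
}

#' Long-format power-profile table
#'
#' One row per (meta-analysis, delta) plus rows for the observed-effect
#' power (delta = NA), suitable for CSV export and re-plotting.
#'
#' @inheritParams median_power
#' @return data.frame with columns `meta_id`, `delta`, `power`.
#' @export
meta_power_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(meta_id = p$meta_id,
               delta = c(p$delta_grid, NA_real_),
               power = c(p$power_at_delta, p$power_at_observed))))
}
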