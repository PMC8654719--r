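# Empirical effect-size benchmarks.
#
# Small/medium/large benchmarks are defined as the 25th/50th/75th
# percentiles of the distribution of absolute effect magnitudes in a
# literature, following the rank-ordering approach used for field-specific
# effect-size guidelines. Quantiles use linear interpolation between order
# statistics at plotting positions (k-1)/(n-1) (stats::quantile type 7);
# other definitions differ at small n, so the type is exposed.

#' Percentile benchmarks with shape descriptives for one distribution
#'
#' @param values non-negative effect magnitudes (at least 4).
#' @param label name for the (sub)distribution summarized.
#' @param quantile_type interpolation rule passed to [stats::quantile()];
#'   default 7 (plotting position (k-1)/(n-1)).
#' @param moment_type `"population"` (biased moment estimators g1, g2;
#'   default) or `"sample"` (bias-corrected G1, G2).
#' @return object of class `benchmark_triple`: list with `label`,
#'   `n_effects`, `q25`, `q50`, `q75`, `skewness`, `kurtosis_excess`.
#' @examples
#' benchmark_quantiles(c(1, 2, 3, 4, 5))   # (2, 3, 4)
#' @export
benchmark_quantiles <- function(values, label = "overall", quantile_type = 7,
                                moment_type = c("population", "sample")) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop("at least 4 values are required to compute benchmarks", call. = FALSE)
  q <- unname(stats::quantile(values, probs = c(0.25, 0.50, 0.75),
                              type = quantile_type))
  mo <- tryCatch(es_moments(values, type = moment_type),
                 error = function(e) c(skewness = NA_real_,
                                       kurtosis_excess = NA_real_))
  res <- list(label = label, n_effects = length(values),
              q25 = q[1], q50 = q[2], q75 = q[3],
              skewness = unname(mo[1]), kurtosis_excess = unname(mo[2]),
              insufficient = FALSE)
  class(res) <- "benchmark_triple"
  res
}

#' @export
print.benchmark_triple <- function(x, ...) {
  cat(sprintf("Effect-size benchmarks [%s] (n = %d)\n", x$label, x$n_effects))
  if (isTRUE(x$insufficient)) {
    cat("  insufficient data (< 4 records)\n")
    return(invisible(x))
  }
  cat(sprintf("  small  (q25): %.3f\n  medium (q50): %.3f\n  large  (q75): %.3f\n",
              x$q25, x$q50, x$q75))
  cat(sprintf("  skewness: %.2f   excess kurtosis: %.2f\n",
              x$skewness, x$kurtosis_excess))
  invisible(x)
}

#' Moment-based skewness and excess kurtosis
#'
#' Population-moment estimators g1 = m3 / m2^(3/2) and g2 = m4 / m2^2 - 3,
#' with mk the k-th central sample moment; the `"sample"` type applies the
#' usual bias corrections. Computed via [e1071::skewness()] /
#' [e1071::kurtosis()].
#'
#' @param values numeric vector, at least 4 values with nonzero variance.
#' @param type `"population"` (default) or `"sample"`.
#' @return named numeric vector `c(skewness, kurtosis_excess)`.
#' @export
es_moments <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop("at least 4 values are required for moment estimates", call. = FALSE)
  if (stats::var(values) == 0)
    stop("zero variance: skewness and kurtosis are undefined", call. = FALSE)
  tp <- if (type == "population") 1L else 2L
  c(skewness = e1071::skewness(values, type = tp),
    kurtosis_excess = e1071::kurtosis(values, type = tp))
}

#' Benchmarks by subgroup
#'
#' Computes one benchmark triple per non-unknown level of a grouping
#' variable, on effect magnitudes. Records with level `"unknown"` are not
#' silently dropped: their count is reported in the `n_unknown` attribute.
#' Subgroups with fewer than 4 records are returned flagged `insufficient`
#' rather than failing the whole call.
#'
#' @param records a harmonized, cleaned `effects_df`.
#' @param by grouping column: `"vessel_bed"`, `"modality"` or
#'   `"bio_category"`.
#' @inheritParams benchmark_quantiles
#' @return named list of `benchmark_triple` objects (one per level present),
#'   with attribute `n_unknown`.
#' @export
subgroup_benchmarks <- function(records, by = c("vessel_bed", "modality",
                                                "bio_category"),
                                quantile_type = 7,
                                moment_type = c("population", "sample")) {
  by <- match.arg(by)
  records <- validate_effects(as.data.frame(records))
  lev <- records[[by]]
  known <- records[lev != "unknown", , drop = FALSE]
  out <- lapply(split(magnitudes(known), known[[by]]), function(v) {
    if (length(v) < 4) {
      res <- list(label = NA_character_, n_effects = length(v),
                  q25 = NA_real_, q50 = NA_real_, q75 = NA_real_,
                  skewness = NA_real_, kurtosis_excess = NA_real_,
                  insufficient = TRUE)
      class(res) <- "benchmark_triple"
      return(res)
    }
    benchmark_quantiles(v, quantile_type = quantile_type,
                        moment_type = moment_type)
  })
  for (nm in names(out)) out[[nm]]$label <- nm
  attr(out, "n_unknown") <- sum(lev == "unknown")
  attr(out, "by") <- by
  out
}

#' Flatten benchmark triples into a report table
#'
#' @param ... `benchmark_triple` objects and/or lists of them (e.g. the
#'   output of [subgroup_benchmarks()]).
#' @return data.frame with one row per triple: label, n_effects, q25, q50,
#'   q75, skewness, kurtosis_excess, insufficient.
#' @export
benchmark_table <- function(...) {
  items <- list(...)
  flat <- list()
  for (it in items) {
    if (inherits(it, "benchmark_triple")) flat[[length(flat) + 1]] <- it
    else flat <- c(flat, it)
  }
  do.call(rbind, lapply(flat, function(b)
    data.frame(label = b$label, n_effects = b$n_effects,
               q25 = b$q25, q50 = b$q50, q75 = b$q75,
               skewness = b$skewness, kurtosis_excess = b$kurtosis_excess,
               insufficient = isTRUE(b$insufficient))))
}

#' Histogram bin counts of effect magnitudes
#'
#' Tabular form of the magnitude frequency distribution, for re-plotting.
#'
#' @param values non-negative magnitudes.
#' @param binwidth bin width on the magnitude scale (default 0.25).
#' @return data.frame with `bin_left`, `bin_right`, `count`.
#' @export
magnitude_histogram <- function(values, binwidth = 0.25) {
  values <- as.numeric(values)
  breaks <- seq(0, max(values, binwidth) + binwidth, by = binwidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(bin_left = utils::head(h$breaks, -1),
             bin_right = h$breaks[-1], count = h$counts)
}
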