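# Synthetic clustered effect-size literatures with known ground truth.
#
# The generator emulates the empirical features of an extracted
# effect-size corpus: ~40 meta-analyses (clusters) of correlated effects
# totalling ~750 rows, a right-skewed lognormal magnitude distribution
# (median 0.69, sdlog chosen so the 75th/50th percentile ratio matches
# 1.21/0.69), group sizes with medians near 21/20, publication years
# 1990-2021, a weak negative magnitude-vs-log-sample-size slope, and
# planted rule-violating rows (duplicates and |es| > 8 outliers) for
# exercising the cleaning stage.

#' Configuration for the synthetic effect-size generator
#'
#' Defaults reproduce the corpus-level features above; ground-truth
#' quantiles of the marginal magnitude law are available in closed form
#' (exact when both injected slopes are zero; with nonzero slopes they
#' describe the unperturbed law and the covariate terms add a small
#' mean-zero perturbation).
#'
#' @param n_meta number of clusters (meta-analyses), default 40.
#' @param total_effects number of genuine effect rows before planting
#'   violations, default 752.
#' @param magnitude_law `"lognormal"` (default) or `"gamma"`.
#' @param magnitude_median median of the marginal magnitude law,
#'   default 0.69.
#' @param magnitude_sigma lognormal sdlog (or gamma shape when
#'   `magnitude_law = "gamma"`); default `log(1.21/0.69)/qnorm(0.75)`
#'   (about 0.833), matching the large/medium benchmark ratio.
#' @param cluster_sd sd of the per-cluster random effect on log magnitude
#'   (within-meta correlation), default 0.3; must be < `magnitude_sigma`
#'   for the lognormal law (residual sd is
#'   `sqrt(magnitude_sigma^2 - cluster_sd^2)`).
#' @param sign_negative_prob fraction of negative signed effects,
#'   default 0.35.
#' @param year_range inclusive publication-year interval,
#'   default c(1990, 2021).
#' @param year_slope injected true slope of magnitude on year, default 0.
#' @param logn_slope injected true slope of magnitude on log10 total
#'   sample size, default -0.19.
#' @param n_median_treatment,n_median_control medians of the discretized
#'   lognormal group-size laws, defaults 21 and 20, truncated at 5.
#' @param n_sigma sdlog of the group-size law, default 0.45.
#' @param frac_hedges_g fraction of rows labelled Hedges' g (with sample
#'   sizes, convertible), default 0.3.
#' @param frac_g_missing_n fraction of rows labelled Hedges' g with no
#'   sample sizes (kept as g downstream), default 0.04.
#' @param dup_count planted duplicate rows, default 6.
#' @param outlier_count planted |es| > 8 rows, default 2.
#' @param meta_se_median,meta_se_sigma median and sdlog of the lognormal
#'   law for meta-summary standard errors, defaults 0.18 and 0.5.
#' @param seed integer seed driving all draws.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_meta = 40, total_effects = 752,
                             magnitude_law = c("lognormal", "gamma"),
                             magnitude_median = 0.69,
                             magnitude_sigma = log(1.21 / 0.69) /
                               stats::qnorm(0.75),
                             cluster_sd = 0.3,
                             sign_negative_prob = 0.35,
                             year_range = c(1990, 2021),
                             year_slope = 0, logn_slope = -0.19,
                             n_median_treatment = 21, n_median_control = 20,
                             n_sigma = 0.45,
                             frac_hedges_g = 0.3, frac_g_missing_n = 0.04,
                             dup_count = 6, outlier_count = 2,
                             meta_se_median = 0.18, meta_se_sigma = 0.5,
                             seed = 1) {
  magnitude_law <- match.arg(magnitude_law)
  if (n_meta < 1 || total_effects < n_meta)
    stop("need total_effects >= n_meta >= 1", call. = FALSE)
  if (magnitude_median <= 0 || magnitude_sigma <= 0)
    stop("magnitude law parameters must be positive", call. = FALSE)
  if (magnitude_law == "lognormal" && cluster_sd >= magnitude_sigma)
    stop("cluster_sd must be smaller than magnitude_sigma", call. = FALSE)
  if (sign_negative_prob < 0 || sign_negative_prob > 1)
    stop("sign_negative_prob must be in [0, 1]", call. = FALSE)
  if (dup_count < 0 || outlier_count < 0)
    stop("planted counts must be non-negative", call. = FALSE)
  cfg <- list(n_meta = as.integer(n_meta),
              total_effects = as.integer(total_effects),
              magnitude_law = magnitude_law,
              magnitude_median = magnitude_median,
              magnitude_sigma = magnitude_sigma, cluster_sd = cluster_sd,
              sign_negative_prob = sign_negative_prob,
              year_range = as.integer(year_range),
              year_slope = year_slope, logn_slope = logn_slope,
              n_median_treatment = n_median_treatment,
              n_median_control = n_median_control, n_sigma = n_sigma,
              frac_hedges_g = frac_hedges_g,
              frac_g_missing_n = frac_g_missing_n,
              dup_count = as.integer(dup_count),
              outlier_count = as.integer(outlier_count),
              meta_se_median = meta_se_median,
              meta_se_sigma = meta_se_sigma,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

.truth_quantiles <- function(cfg) {
  p <- c(0.25, 0.50, 0.75)
  if (cfg$magnitude_law == "lognormal") {
    stats::qlnorm(p, meanlog = log(cfg$magnitude_median),
                  sdlog = cfg$magnitude_sigma)
  } else {
    shape <- cfg$magnitude_sigma
    scale <- cfg$magnitude_median / stats::qgamma(0.5, shape = shape)
    stats::qgamma(p, shape = shape, scale = scale)
  }
}

#' Generate a synthetic effects table with ground truth
#'
#' Draws `total_effects` genuine records allocated over `n_meta` clusters
#' (every cluster non-empty), then appends `dup_count` exact copies of
#' existing rows flagged as duplicates and `outlier_count` rows with
#' magnitude above 8, and shuffles the row order. A configurable fraction
#' of rows is labelled Hedges' g: their stored value is the d-scale draw
#' times the correction factor for their sample sizes, so harmonization
#' recovers the d scale exactly; a smaller fraction is g-labelled with no
#' sample sizes (unconvertible pass-throughs). Byte-identical output for
#' identical seeds.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (an `effects_df` of
#'   `total_effects + dup_count + outlier_count` rows) and `truth` (list:
#'   `true_q25/q50/q75` of the marginal magnitude law, `true_year_slope`,
#'   `true_logn_slope`, planted counts).
#' @export
generate_effect_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    n <- cfg$total_effects
    G <- cfg$n_meta
    meta_labels <- sprintf("M%03d", seq_len(G))
    # every cluster gets >= 1 row; remainder multinomial with mild
    # size heterogeneity between meta-analyses
    w <- stats::rgamma(G, shape = 4)
    sizes <- as.vector(stats::rmultinom(1, n - G, prob = w)) + 1L
    meta_id <- rep(meta_labels, times = sizes)

    rln_n <- function(n, med) pmax(5L, as.integer(round(
      stats::rlnorm(n, meanlog = log(med), sdlog = cfg$n_sigma))))
    n1 <- rln_n(n, cfg$n_median_treatment)
    n2 <- rln_n(n, cfg$n_median_control)
    year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                   replace = TRUE)

    b_cluster <- stats::rnorm(G, 0, cfg$cluster_sd)
    if (cfg$magnitude_law == "lognormal") {
      resid_sd <- sqrt(cfg$magnitude_sigma^2 - cfg$cluster_sd^2)
      m <- exp(log(cfg$magnitude_median) + rep(b_cluster, times = sizes) +
                 stats::rnorm(n, 0, resid_sd))
    } else {
      shape <- cfg$magnitude_sigma
      scale <- cfg$magnitude_median / stats::qgamma(0.5, shape = shape)
      m <- stats::rgamma(n, shape = shape, scale = scale) *
        exp(rep(b_cluster, times = sizes))
    }
    # covariate-linked perturbations, centered so the marginal law is
    # shifted as little as possible; magnitudes floored just above zero
    x_logn <- log10(n1 + n2)
    x_year <- year
    m <- m + cfg$logn_slope *
      (x_logn - log10(cfg$n_median_treatment + cfg$n_median_control)) +
      cfg$year_slope * (x_year - mean(cfg$year_range))
    # keep genuine rows inside the |es| <= 8 cleaning rule so the planted
    # violations are exactly the rows the cleaner removes; capping does not
    # move any quantile below the cap
    m <- pmin(pmax(m, 0.01), 7.99)

    sgn <- ifelse(stats::runif(n) < cfg$sign_negative_prob, -1, 1)
    d_val <- sgn * m

    u <- stats::runif(n)
    metric <- ifelse(u < cfg$frac_g_missing_n, "g_no_n",
                     ifelse(u < cfg$frac_g_missing_n + cfg$frac_hedges_g,
                            "hedges_g", "cohens_d"))
    es_value <- d_val
    es_metric <- rep("cohens_d", n)
    is_g <- metric == "hedges_g"
    es_value[is_g] <- d_val[is_g] *
      hedges_correction(n1[is_g] + n2[is_g])
    es_metric[is_g | metric == "g_no_n"] <- "hedges_g"
    n1_out <- n1; n2_out <- n2
    n1_out[metric == "g_no_n"] <- NA_integer_
    n2_out[metric == "g_no_n"] <- NA_integer_

    se_i <- sqrt(1 / n1 + 1 / n2 + d_val^2 / (2 * (n1 + n2)))
    ci_lower <- es_value - stats::qnorm(0.975) * se_i
    ci_upper <- es_value + stats::qnorm(0.975) * se_i

    vessel_bed <- sample(c("macro", "micro", "unknown"), n, replace = TRUE,
                         prob = c(0.72, 0.27, 0.01))
    modality <- sample(c("ultrasound", "plethysmography", "laser_doppler",
                         "other"), n, replace = TRUE,
                       prob = c(0.74, 0.13, 0.08, 0.05))
    bio_category <- sample(c("exercise", "supplement_diet",
                             "pathophysiology", "other"), n, replace = TRUE,
                           prob = c(0.20, 0.37, 0.36, 0.07))

    genuine <- effect_records(
      es_value = es_value, es_metric = es_metric, meta_id = meta_id,
      ci_lower = ci_lower, ci_upper = ci_upper,
      n_treatment = n1_out, n_control = n2_out, year = year,
      vessel_bed = vessel_bed, modality = modality,
      bio_category = bio_category, is_duplicate = FALSE)

    extra <- NULL
    if (cfg$dup_count > 0) {
      dup_rows <- genuine[sample.int(n, cfg$dup_count, replace = FALSE), ,
                          drop = FALSE]
      dup_rows$is_duplicate <- TRUE
      extra <- dup_rows
    }
    if (cfg$outlier_count > 0) {
      mag_out <- stats::runif(cfg$outlier_count, 8.5, 12)
      out_rows <- effect_records(
        es_value = mag_out *
          ifelse(stats::runif(cfg$outlier_count) < 0.5, -1, 1),
        es_metric = "cohens_d",
        meta_id = sample(meta_labels, cfg$outlier_count, replace = TRUE),
        year = sample(seq(cfg$year_range[1], cfg$year_range[2]),
                      cfg$outlier_count, replace = TRUE),
        n_treatment = rln_n(cfg$outlier_count, cfg$n_median_treatment),
        n_control = rln_n(cfg$outlier_count, cfg$n_median_control))
      extra <- if (is.null(extra)) out_rows else rbind(extra, out_rows)
    }
    records <- if (is.null(extra)) genuine else rbind(genuine, extra)
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    records$record_id <- sprintf("E%04d", seq_len(nrow(records)))
    rownames(records) <- NULL

    tq <- .truth_quantiles(cfg)
    list(records = validate_effects(records),
         truth = list(true_q25 = tq[1], true_q50 = tq[2], true_q75 = tq[3],
                      true_year_slope = cfg$year_slope,
                      true_logn_slope = cfg$logn_slope,
                      n_genuine = n, dup_count = cfg$dup_count,
                      outlier_count = cfg$outlier_count))
  })
}

#' Generate a synthetic meta-summary table with known standard errors
#'
#' One summary effect per cluster: a signed effect with a lognormal
#' standard error and an exactly symmetric 95% CI, so that CI-derived
#' standard errors reproduce the generated ones to numerical precision.
#' The generator uses a seed offset from the effects table's so both
#' tables are independently reproducible from one configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with `metas` (data.frame: meta_id, summary_es, ci_lower,
#'   ci_upper, se) and `truth` (list with `true_se` per meta).
#' @export
generate_meta_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  .with_seed(cfg$seed + 1L, {
    G <- cfg$n_meta
    se <- stats::rlnorm(G, meanlog = log(cfg$meta_se_median),
                        sdlog = cfg$meta_se_sigma)
    mag <- stats::rlnorm(G, meanlog = log(cfg$magnitude_median / 2),
                         sdlog = cfg$magnitude_sigma)
    sgn <- ifelse(stats::runif(G) < cfg$sign_negative_prob, -1, 1)
    es <- sgn * mag
    z <- stats::qnorm(0.975)
    metas <- data.frame(meta_id = sprintf("M%03d", seq_len(G)),
                        summary_es = es,
                        ci_lower = es - z * se, ci_upper = es + z * se,
                        se = se, stringsAsFactors = FALSE)
    list(metas = metas, truth = list(true_se = se))
  })
}

#' Write a meta-summary table to CSV
#'
#' @param metas data.frame as produced by [generate_meta_dataset()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_meta_summaries <- function(metas, path) {
  utils::write.csv(metas, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}
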