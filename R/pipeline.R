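# End-to-end orchestration: clean -> harmonize -> benchmarks ->
# correlates -> power -> meta-power, with a report bundle and a manifest
# sufficient to re-run the pipeline bit-identically.

#' Pipeline configuration
#'
#' Every field has a documented default reproducing the reference analysis
#' settings: outlier threshold 8, LOESS span 0.75, 10,000 bootstrap
#' samples, alpha 0.05 two-tailed, power levels 0.7/0.8/0.9, delta grid
#' 0.1-1.0.
#'
#' @param effects either a path to an effects CSV or an `effects_df`.
#' @param metas either a path to a meta-summary CSV or a data.frame;
#'   `NULL` skips the meta-power stage.
#' @param out_dir output directory for the report bundle; `NULL` returns
#'   results without writing files.
#' @param outlier_threshold cleaning rule magnitude, default 8.
#' @param quantile_type quantile interpolation rule, default 7.
#' @param log_base base of the sample-size logarithm covariate, default 10.
#' @param n_boot clustered-bootstrap replicates, default 10000.
#' @param span LOESS span, default 0.75.
#' @param power_levels targets for the sample-size curve,
#'   default c(0.7, 0.8, 0.9).
#' @param d_grid effect sizes for the power tables; `NULL` (default) uses
#'   the small/medium/large benchmarks estimated from the data.
#' @param delta_grid assumed true effects for meta-power profiles,
#'   default 0.1-1.0 step 0.1.
#' @param alpha type-I error rate, default 0.05.
#' @param tails `"two"` (default) or `"one"`.
#' @param seed integer seed for all stochastic stages (the bootstrap).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(effects, metas = NULL, out_dir = NULL,
                            outlier_threshold = 8, quantile_type = 7,
                            log_base = 10, n_boot = 10000, span = 0.75,
                            power_levels = c(0.7, 0.8, 0.9), d_grid = NULL,
                            delta_grid = seq(0.1, 1.0, by = 0.1),
                            alpha = 0.05, tails = "two", seed = 1) {
  cfg <- list(effects = effects, metas = metas, out_dir = out_dir,
              outlier_threshold = outlier_threshold,
              quantile_type = quantile_type, log_base = log_base,
              n_boot = n_boot, span = span, power_levels = power_levels,
              d_grid = d_grid, delta_grid = delta_grid, alpha = alpha,
              tails = tails, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full benchmark-and-power analysis
#'
#' Stages: (1) read and clean the effects table with an auditable count of
#' removals; (2) harmonize all records to the Cohen's d scale; (3) derive
#' percentile benchmarks overall and by vessel bed, modality and
#' biological category; (4) regress effect magnitude on publication year
#' and on the log total sample size with cluster-robust and
#' clustered-bootstrap inference, plus a LOESS year trend; (5) compute
#' required sample sizes at the benchmark effects for paired and
#' independent designs, and power at the median observed group sizes;
#' (6) profile the power of each meta-analysis over the delta grid.
#' When `out_dir` is set, each stage writes CSV/JSON reports and a
#' manifest recording the configuration, seed and stage counts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly when writing) list with elements `cleaning`,
#'   `harmonized`, `benchmarks`, `regressions`, `loess`, `power`,
#'   `meta_power`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  effects <- if (is.character(cfg$effects)) read_effects(cfg$effects)
             else validate_effects(as.data.frame(cfg$effects))

  cleaning <- clean_effects(effects, outlier_threshold = cfg$outlier_threshold)
  harmonized <- harmonize_to_d(cleaning$retained)
  mag <- magnitudes(harmonized)

  overall <- benchmark_quantiles(mag, label = "overall",
                                 quantile_type = cfg$quantile_type)
  by_bed <- subgroup_benchmarks(harmonized, "vessel_bed",
                                quantile_type = cfg$quantile_type)
  by_mod <- subgroup_benchmarks(harmonized, "modality",
                                quantile_type = cfg$quantile_type)
  by_bio <- subgroup_benchmarks(harmonized, "bio_category",
                                quantile_type = cfg$quantile_type)
  bench_tab <- benchmark_table(overall, by_bed, by_mod, by_bio)

  n_total <- harmonized$n_treatment + harmonized$n_control
  has_n <- !is.na(n_total)
  x_logn <- log(n_total[has_n], base = cfg$log_base)
  has_year <- !is.na(harmonized$year)

  reg_year <- fit_cluster_ols(mag[has_year], harmonized$year[has_year],
                              harmonized$meta_id[has_year])
  boot_year <- cluster_bootstrap_ci(mag[has_year],
                                    harmonized$year[has_year],
                                    harmonized$meta_id[has_year],
                                    n_replicates = cfg$n_boot,
                                    seed = cfg$seed)
  reg_logn <- fit_cluster_ols(mag[has_n], x_logn,
                              harmonized$meta_id[has_n])
  boot_logn <- cluster_bootstrap_ci(mag[has_n], x_logn,
                                    harmonized$meta_id[has_n],
                                    n_replicates = cfg$n_boot,
                                    seed = cfg$seed + 1L)
  regressions <- data.frame(
    covariate = c("year", paste0("log", cfg$log_base, "_n_total")),
    beta = c(reg_year$beta, reg_logn$beta),
    se_adj = c(reg_year$se_adj, reg_logn$se_adj),
    ci_lower = c(reg_year$ci_lower, reg_logn$ci_lower),
    ci_upper = c(reg_year$ci_upper, reg_logn$ci_upper),
    p_value = c(reg_year$p_value, reg_logn$p_value),
    boot_ci_lower = c(boot_year$ci_lower, boot_logn$ci_lower),
    boot_ci_upper = c(boot_year$ci_upper, boot_logn$ci_upper),
    n_obs = c(reg_year$n_obs, reg_logn$n_obs),
    n_clusters = c(reg_year$n_clusters, reg_logn$n_clusters))
  loess_tab <- loess_curve(harmonized$year[has_year], mag[has_year],
                           span = cfg$span)

  d_grid <- cfg$d_grid
  if (is.null(d_grid)) d_grid <- c(overall$q25, overall$q50, overall$q75)
  pc_paired <- power_curve("paired", d_grid, cfg$power_levels, cfg$alpha,
                           cfg$tails)
  pc_two <- power_curve("two_sample", d_grid, cfg$power_levels, cfg$alpha,
                        cfg$tails)
  power_tab <- rbind(cbind(design = "paired", pc_paired),
                     cbind(design = "two_sample", pc_two))
  med_n1 <- stats::median(harmonized$n_treatment, na.rm = TRUE)
  med_n2 <- stats::median(harmonized$n_control, na.rm = TRUE)
  power_at_median_n <- data.frame(
    d = d_grid,
    n1 = med_n1, n2 = med_n2,
    power = power_two_sample(d_grid, med_n1, med_n2, cfg$alpha, cfg$tails))

  meta_res <- NULL
  if (!is.null(cfg$metas)) {
    metas <- if (is.character(cfg$metas)) read_meta_summaries(cfg$metas)
             else cfg$metas
    profiles <- meta_power_profiles(metas, cfg$delta_grid, cfg$alpha)
    meta_res <- list(profiles = profiles,
                     table = meta_power_table(profiles),
                     medians = median_power(profiles))
  }

  manifest <- list(
    # out_dir is where the bundle lives, not part of what it computed
    config = cfg[setdiff(names(cfg), c("effects", "metas", "out_dir"))],
    effects_input = if (is.character(cfg$effects)) cfg$effects else "<in-memory>",
    metas_input = if (is.character(cfg$metas)) cfg$metas
                  else if (is.null(cfg$metas)) NULL else "<in-memory>",
    seed = cfg$seed,
    counts = list(n_input = cleaning$n_input,
                  n_duplicates_removed = cleaning$n_duplicates_removed,
                  n_outliers_removed = cleaning$n_outliers_removed,
                  n_retained = nrow(cleaning$retained),
                  n_unconverted_g = sum(harmonized$conversion_flag ==
                                          "unconverted_g", na.rm = TRUE),
                  n_meta = if (is.null(meta_res)) 0L
                           else length(meta_res$profiles)))

  res <- list(cleaning = cleaning, harmonized = harmonized,
              benchmarks = list(overall = overall, vessel_bed = by_bed,
                                modality = by_mod, bio_category = by_bio,
                                table = bench_tab),
              regressions = regressions,
              regression_fits = list(year = reg_year, log_n = reg_logn),
              loess = loess_tab,
              power = list(table = power_tab,
                           at_median_n = power_at_median_n,
                           median_n = c(n1 = med_n1, n2 = med_n2)),
              meta_power = meta_res,
              manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_cleaning_audit(cleaning, p("cleaning_audit.json"))
    utils::write.csv(bench_tab, p("benchmarks.csv"), row.names = FALSE)
    jsonlite::write_json(bench_tab, p("benchmarks.json"), digits = NA)
    utils::write.csv(regressions, p("regressions.csv"), row.names = FALSE)
    utils::write.csv(loess_tab, p("loess_curve.csv"), row.names = FALSE)
    utils::write.csv(power_tab, p("power_table.csv"), row.names = FALSE)
    utils::write.csv(power_at_median_n, p("power_at_median_n.csv"),
                     row.names = FALSE)
    if (!is.null(meta_res)) {
      utils::write.csv(meta_res$table, p("meta_power_profiles.csv"),
                       row.names = FALSE)
      jsonlite::write_json(meta_res$medians, p("meta_power_medians.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    return(invisible(res))
  }
  res
}
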