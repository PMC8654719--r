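test_that("generation is deterministic and covers every cluster", {
  cfg <- synthetic_config(seed = 5)
  g1 <- generate_effect_dataset(cfg)
  g2 <- generate_effect_dataset(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
  expect_equal(length(unique(g1$records$meta_id)), 40)
  expect_equal(nrow(g1$records), 752 + 6 + 2)

  m1 <- generate_meta_dataset(cfg)
  m2 <- generate_meta_dataset(cfg)
  expect_identical(m1$metas, m2$metas)
  expect_equal(nrow(m1$metas), 40)

  g3 <- generate_effect_dataset(synthetic_config(seed = 6))
  expect_false(identical(g1$records$es_value, g3$records$es_value))
})

test_that("configuration is validated", {
  expect_error(synthetic_config(n_meta = 0), "n_meta")
  expect_error(synthetic_config(total_effects = 10, n_meta = 40), "n_meta")
  expect_error(synthetic_config(magnitude_median = -1), "positive")
  expect_error(synthetic_config(cluster_sd = 2), "cluster_sd")
  expect_error(synthetic_config(sign_negative_prob = 1.4), "sign_negative")
  expect_error(synthetic_config(dup_count = -1), "planted")
})

test_that("cleaning removes exactly the planted violations (pipeline closure)", {
  for (s in c(1, 9, 33)) {
    gen <- generate_effect_dataset(synthetic_config(seed = s))
    res <- clean_effects(gen$records)
    expect_equal(res$n_input, 760)
    expect_equal(res$n_duplicates_removed, 6)
    expect_equal(res$n_outliers_removed, 2)
    expect_equal(nrow(res$retained), 752)
  }
})

test_that("ground-truth quantiles are recovered at large n with zero slopes", {
  cfg <- synthetic_config(n_meta = 50, total_effects = 50000, cluster_sd = 0,
                          logn_slope = 0, frac_g_missing_n = 0,
                          dup_count = 0, outlier_count = 0, seed = 1)
  gen <- generate_effect_dataset(cfg)
  h <- harmonize_to_d(gen$records)
  b <- benchmark_quantiles(magnitudes(h))
  expect_lt(abs(b$q25 - gen$truth$true_q25), 0.01)
  expect_lt(abs(b$q50 - gen$truth$true_q50), 0.01)
  expect_lt(abs(b$q75 - gen$truth$true_q75), 0.01)
  # closed-form truth is the lognormal quantile function
  expect_equal(gen$truth$true_q50, 0.69, tolerance = 1e-12)
  expect_equal(gen$truth$true_q75 / gen$truth$true_q50, 1.21 / 0.69,
               tolerance = 1e-10)
})

test_that("the default corpus emulates the empirical shape and sample sizes", {
  sk <- ku <- med1 <- med2 <- numeric(50)
  for (s in 1:50) {
    gen <- generate_effect_dataset(synthetic_config(seed = 1000 + s))
    h <- harmonize_to_d(clean_effects(gen$records)$retained)
    mo <- es_moments(magnitudes(h))
    sk[s] <- mo[1]; ku[s] <- mo[2]
    med1[s] <- median(h$n_treatment, na.rm = TRUE)
    med2[s] <- median(h$n_control, na.rm = TRUE)
  }
  expect_gte(mean(sk >= 1.5 & sk <= 4 & ku >= 4 & ku <= 16), 0.9)
  expect_lte(abs(median(med1) - 21), 1)
  expect_lte(abs(median(med2) - 20), 1)
})

test_that("harmonization inverts the planted g-labelling exactly", {
  gen <- generate_effect_dataset(synthetic_config(seed = 3,
                                                  frac_g_missing_n = 0))
  res <- clean_effects(gen$records)
  h <- harmonize_to_d(res$retained)
  expect_true(all(h$es_metric == "cohens_d"))
  n_conv <- sum(h$conversion_flag == "converted_from_g", na.rm = TRUE)
  expect_gt(n_conv, 100)  # ~30% of 752
  # converted magnitudes stay within the cleaning rule
  expect_true(all(abs(h$es_value) <= 8.2))
})

test_that("end-to-end recovery: benchmarks and slope inference at study scale", {
  n_rep <- 200
  q50 <- cover_sand <- cover_boot <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    gen <- generate_effect_dataset(synthetic_config(seed = 20000 + s))
    h <- harmonize_to_d(clean_effects(gen$records)$retained)
    b <- benchmark_quantiles(magnitudes(h))
    q50[s] <- b$q50
    nt <- h$n_treatment + h$n_control
    ok <- !is.na(nt)
    fit <- fit_cluster_ols(magnitudes(h)[ok], log10(nt[ok]), h$meta_id[ok])
    cover_sand[s] <- fit$ci_lower <= -0.19 && -0.19 <= fit$ci_upper
    boot <- cluster_bootstrap_ci(magnitudes(h)[ok], log10(nt[ok]),
                                 h$meta_id[ok], n_replicates = 400,
                                 seed = s)
    cover_boot[s] <- boot$ci_lower <= -0.19 && -0.19 <= boot$ci_upper
  }
  expect_lt(abs(median(q50) - 0.69), 0.05)
  expect_gte(mean(cover_sand), 0.90)
  expect_gte(mean(cover_boot), 0.90)
})

test_that("a zero-trend year covariate yields a near-zero slope with coverage", {
  n_rep <- 60
  est <- cover <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    gen <- generate_effect_dataset(synthetic_config(seed = 40000 + s))
    h <- harmonize_to_d(clean_effects(gen$records)$retained)
    fit <- fit_cluster_ols(magnitudes(h), h$year, h$meta_id)
    est[s] <- fit$beta
    cover[s] <- fit$ci_lower <= 0 && 0 <= fit$ci_upper
  }
  expect_lt(abs(mean(est)), 0.005)
  expect_gte(mean(cover), 0.90)
})

test_that("meta summaries are self-consistent and reproducible", {
  gen <- generate_meta_dataset(synthetic_config(seed = 2))
  derived <- se_from_ci(gen$metas$ci_lower, gen$metas$ci_upper)
  expect_equal(derived, gen$metas$se, tolerance = 1e-10)
  expect_equal(gen$metas$se, gen$truth$true_se, tolerance = 1e-12)
  expect_true(any(gen$metas$summary_es < 0) && any(gen$metas$summary_es > 0))
})
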