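test_that("benchmark quantiles match hand interpolation on small cases", {
  b <- benchmark_quantiles(c(1, 2, 3, 4, 5))
  expect_equal(c(b$q25, b$q50, b$q75), c(2, 3, 4))
  expect_equal(b$n_effects, 5)

  b2 <- benchmark_quantiles(c(0, 0, 1, 1))
  expect_equal(c(b2$q25, b2$q50, b2$q75), c(0, 0.5, 1))

  bc <- benchmark_quantiles(rep(2.5, 6))
  expect_equal(c(bc$q25, bc$q50, bc$q75), c(2.5, 2.5, 2.5))
  expect_true(is.na(bc$skewness))  # zero variance: moments undefined

  expect_error(benchmark_quantiles(c(1, 2, 3)), "at least 4")
})

test_that("quantiles agree with an exhaustive hand computation for n <= 12", {
  set.seed(23)
  for (i in 1:25) {
    v <- round(rexp(sample(4:12, 1), rate = 1), 3)
    b <- benchmark_quantiles(v)
    expect_equal(c(b$q25, b$q50, b$q75),
                 hand_quantile(v, c(0.25, 0.5, 0.75)), tolerance = 1e-12)
  }
})

test_that("quantiles are equivariant under increasing transforms", {
  set.seed(31)
  v <- rexp(40)
  # affine maps commute with linear interpolation exactly
  for (i in 1:10) {
    a <- rexp(1); b0 <- rnorm(1)
    b1 <- benchmark_quantiles(v)
    b2 <- benchmark_quantiles(a * v + b0)
    expect_equal(c(b2$q25, b2$q50, b2$q75),
                 a * c(b1$q25, b1$q50, b1$q75) + b0, tolerance = 1e-10)
  }
  # at n where the plotting positions land on order statistics, any
  # monotone transform commutes
  v5 <- sort(rexp(5))
  b1 <- benchmark_quantiles(v5)
  b2 <- benchmark_quantiles(sqrt(v5))
  expect_equal(c(b2$q25, b2$q50, b2$q75),
               sqrt(c(b1$q25, b1$q50, b1$q75)), tolerance = 1e-12)
})

test_that("moment estimators match direct central-moment arithmetic", {
  expect_equal(unname(es_moments(c(0, 0, 0, 1))[1]),
               0.09375 / 0.1875^1.5, tolerance = 1e-12)
  expect_equal(unname(es_moments(c(1, 2, 3, 4, 5))[1]), 0, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:15) {
    v <- rlnorm(sample(5:40, 1))
    expect_equal(unname(es_moments(v)), unname(hand_moments(v)),
                 tolerance = 1e-10)
  }
  expect_error(es_moments(rep(1, 10)), "variance")
  expect_error(es_moments(c(1, 2)), "at least 4")
})

test_that("moments of a large normal sample are near zero", {
  set.seed(99)
  mo <- es_moments(rnorm(200000))
  expect_lt(abs(mo[1]), 0.03)
  expect_lt(abs(mo[2]), 0.06)
})

test_that("estimated quantiles converge to closed-form lognormal quantiles", {
  set.seed(2)
  mu <- log(0.69)
  sigma <- 0.83
  truth <- qlnorm(c(0.25, 0.5, 0.75), mu, sigma)
  for (n in c(2000, 50000)) {
    b <- benchmark_quantiles(rlnorm(n, mu, sigma))
    tol <- 3 / sqrt(n)
    expect_lt(abs(b$q25 - truth[1]), tol)
    expect_lt(abs(b$q50 - truth[2]), tol)
    expect_lt(abs(b$q75 - truth[3]), tol)
  }
})

test_that("subgroup benchmarks split by level and keep unknowns accountable", {
  rec <- effect_records(
    es_value = c(1, 2, 3, 4, 5, 0.5, 0.6, 0.7, 0.4, 2.2),
    es_metric = "cohens_d", meta_id = "M1",
    vessel_bed = c(rep("macro", 5), rep("micro", 4), "unknown"))
  sub <- subgroup_benchmarks(rec, "vessel_bed")
  expect_setequal(names(sub), c("macro", "micro"))
  expect_equal(attr(sub, "n_unknown"), 1)
  expect_equal(c(sub$macro$q25, sub$macro$q50, sub$macro$q75), c(2, 3, 4))
  # macro values stochastically larger than micro here
  expect_gt(sub$macro$q50, sub$micro$q50)

  # a single-level table reproduces the pooled benchmark
  one <- effect_records(c(1, 2, 3, 4, 5), "cohens_d", "M1",
                        vessel_bed = "macro")
  s1 <- subgroup_benchmarks(one, "vessel_bed")
  pooled <- benchmark_quantiles(magnitudes(one))
  expect_equal(length(s1), 1)
  expect_equal(s1$macro$q50, pooled$q50)

  # undersized subgroup is flagged, others unaffected
  rec2 <- effect_records(
    es_value = c(1, 2, 3, 4, 5, 0.5, 0.6, 0.7),
    es_metric = "cohens_d", meta_id = "M1",
    modality = c(rep("ultrasound", 5), rep("laser_doppler", 3)))
  s2 <- subgroup_benchmarks(rec2, "modality")
  expect_true(s2$laser_doppler$insufficient)
  expect_true(is.na(s2$laser_doppler$q50))
  expect_false(s2$ultrasound$insufficient)
  expect_equal(s2$ultrasound$q50, 3)
})

test_that("a macro-shifted synthetic mixture yields a larger macro median", {
  set.seed(17)
  n <- 400
  bed <- sample(c("macro", "micro"), n, TRUE)
  mag <- rlnorm(n, meanlog = ifelse(bed == "macro", log(0.76), log(0.49)),
                sdlog = 0.6)
  rec <- effect_records(mag, "cohens_d", "M1", vessel_bed = bed)
  sub <- subgroup_benchmarks(rec, "vessel_bed")
  expect_gt(sub$macro$q50, sub$micro$q50)
})

test_that("benchmark_table flattens triples and the histogram counts everything", {
  rec <- tiny_effects()
  tab <- benchmark_table(benchmark_quantiles(magnitudes(c(1, 2, 3, 4)),
                                             label = "overall"),
                         subgroup_benchmarks(rec, "vessel_bed"))
  expect_true(all(c("label", "n_effects", "q25", "q50", "q75") %in%
                    names(tab)))
  expect_equal(tab$label[1], "overall")

  v <- c(0.1, 0.3, 0.6, 1.4, 2.2)
  hh <- magnitude_histogram(v, binwidth = 0.5)
  expect_equal(sum(hh$count), length(v))
  expect_true(all(hh$bin_right - hh$bin_left - 0.5 < 1e-12))
})
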