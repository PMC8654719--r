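test_that("CSV round trip preserves records and input order", {
  rec <- tiny_effects()
  path <- withr::local_tempfile(fileext = ".csv")
  write_effects(rec, path)
  back <- read_effects(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$es_value, rec$es_value)
  expect_equal(back$meta_id, rec$meta_id)
  expect_equal(back$es_metric, rec$es_metric)
  expect_equal(back$n_treatment, rec$n_treatment)
  expect_identical(back$record_id, rec$record_id)
})

test_that("schema and row-level errors name the problem", {
  rec <- tiny_effects()
  path <- withr::local_tempfile(fileext = ".csv")
  write_effects(rec[setdiff(names(rec), "es_metric")], path)
  expect_error(read_effects(path), "es_metric")

  rec2 <- as.data.frame(tiny_effects())
  rec2$vessel_bed[2] <- "brachial ultrasound"
  write_effects(rec2, path)
  expect_error(read_effects(path), "row 2.*vessel_bed")

  rec3 <- as.data.frame(tiny_effects())
  rec3$es_value <- as.character(rec3$es_value)
  rec3$es_value[3] <- "about 0.9"
  utils::write.csv(rec3, path, row.names = FALSE, na = "")
  expect_error(read_effects(path), "row 3.*es_value")

  expect_error(read_effects(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("missing optional columns map to unknown/absent defaults", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("es_value,es_metric,meta_id",
               "0.5,cohens_d,M1",
               "-0.2,hedges_g,M2"), path)
  rec <- read_effects(path)
  expect_equal(rec$vessel_bed, c("unknown", "unknown"))
  expect_equal(rec$modality, c("unknown", "unknown"))
  expect_true(all(is.na(rec$ci_lower)))
  expect_false(any(rec$is_duplicate))
})

test_that("validation enforces the record invariants", {
  expect_error(effect_records(0.5, "cohens_z", "M1"), "es_metric")
  expect_error(effect_records(0.5, "cohens_d", "M1", n_treatment = 0L),
               "n_treatment")
  expect_error(effect_records(0.5, "cohens_d", "M1",
                              ci_lower = 0.6, ci_upper = 0.9),
               "bracket")
})

test_that("cleaning removes flagged duplicates then outliers, conserving counts", {
  rec <- effect_records(
    es_value = c(0.4, 0.4, 9.0, -0.7, 1.0),
    es_metric = "cohens_d", meta_id = "M1",
    is_duplicate = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  res <- clean_effects(rec)
  expect_equal(nrow(res$retained), 3)
  expect_equal(res$n_duplicates_removed, 1)
  expect_equal(res$n_outliers_removed, 1)
  expect_equal(res$n_input,
               nrow(res$retained) + res$n_duplicates_removed +
                 res$n_outliers_removed)
  expect_equal(res$retained$es_value, c(0.4, -0.7, 1.0))

  empty <- clean_effects(rec[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(empty$n_duplicates_removed, 0)
  expect_equal(empty$n_outliers_removed, 0)

  expect_error(clean_effects(rec, outlier_threshold = 0), "positive")
})

test_that("the outlier rule is strict: |es| exactly at the threshold survives", {
  rec <- effect_records(c(8, -8, 8.0001), "cohens_d", "M1")
  res <- clean_effects(rec)
  expect_equal(nrow(res$retained), 2)
  expect_equal(res$n_outliers_removed, 1)
})

test_that("cleaning is idempotent and conserves counts on random tables", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(0:80, 1)
    rec <- effect_records(
      es_value = stats::rt(n, df = 3) * 3,
      es_metric = sample(c("cohens_d", "hedges_g"), max(n, 1), TRUE)[seq_len(n)],
      meta_id = sample(paste0("M", 1:5), max(n, 1), TRUE)[seq_len(n)],
      is_duplicate = sample(c(TRUE, FALSE), max(n, 1), TRUE,
                            prob = c(0.1, 0.9))[seq_len(n)])
    res <- clean_effects(rec)
    expect_equal(res$n_input, nrow(res$retained) + res$n_duplicates_removed +
                   res$n_outliers_removed)
    expect_false(any(res$retained$is_duplicate))
    expect_true(all(abs(res$retained$es_value) <= 8))
    twice <- clean_effects(res$retained)
    expect_equal(twice$retained, res$retained)
    expect_equal(twice$n_duplicates_removed + twice$n_outliers_removed, 0)
  }
})

test_that("optional exact-tuple duplicate detection is off by default", {
  rec <- effect_records(
    es_value = c(0.5, 0.5), es_metric = "cohens_d", meta_id = c("M1", "M2"),
    ci_lower = 0.1, ci_upper = 0.9, n_treatment = 10L, n_control = 10L)
  expect_equal(nrow(clean_effects(rec)$retained), 2)
  auto <- clean_effects(rec, auto_detect_duplicates = TRUE)
  expect_equal(nrow(auto$retained), 1)
  expect_equal(auto$n_duplicates_removed, 1)
})

test_that("magnitudes takes absolute values, preserves order, and is idempotent", {
  expect_equal(magnitudes(c(-0.5, 0.3)), c(0.5, 0.3))
  expect_equal(magnitudes(numeric(0)), numeric(0))
  expect_equal(magnitudes(c(-1.21)), 1.21)
  rec <- tiny_effects()
  expect_equal(magnitudes(rec), abs(rec$es_value))
  set.seed(7)
  v <- rnorm(50)
  expect_equal(magnitudes(magnitudes(v)), magnitudes(v))
  expect_true(all(magnitudes(v) >= abs(v) - 1e-15))
})

test_that("the cleaning audit JSON reports all counts", {
  rec <- effect_records(c(0.4, 9.5), "cohens_d", "M1",
                        is_duplicate = c(FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_cleaning_audit(clean_effects(rec), path)
  audit <- jsonlite::read_json(path)
  expect_equal(audit$n_input, 2)
  expect_equal(audit$n_outliers_removed, 1)
  expect_equal(audit$n_retained, 1)
})
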