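#' @keywords internal
"_PACKAGE"

# Enum vocabularies for the categorical metadata carried by each effect record.
.es_metrics <- c("cohens_d", "hedges_g")
.vessel_beds <- c("macro", "micro", "unknown")
.modalities <- c("ultrasound", "plethysmography", "laser_doppler", "other",
                 "unknown")
.bio_categories <- c("exercise", "supplement_diet", "pathophysiology", "other",
                     "unknown")

.required_cols <- c("es_value", "es_metric", "meta_id")

#' Construct a validated table of effect-size records
#'
#' An effects table holds one row per standardized mean difference (SMD)
#' extracted from a meta-analysis. Required fields are the signed effect
#' value, its metric (`"cohens_d"` or `"hedges_g"`) and the identifier of
#' the parent meta-analysis (the cluster label). Optional fields -- 95% CI
#' bounds, group sample sizes, publication year, vessel bed, measurement
#' modality, biological category, duplicate flag -- are filled with
#' `NA`/`"unknown"`/`FALSE` defaults when absent, so that subgroup analyses
#' can exclude unknowns without dropping rows from the pooled distribution.
#'
#' @param es_value numeric vector of signed SMD values.
#' @param es_metric character vector, each `"cohens_d"` or `"hedges_g"`.
#' @param meta_id cluster label (parent meta-analysis) per record.
#' @param record_id optional identifiers; defaults to `E0001, E0002, ...`.
#' @param ci_lower,ci_upper optional signed 95% interval bounds.
#' @param n_treatment,n_control optional positive integer group sizes.
#' @param year optional integer publication year.
#' @param vessel_bed one of `"macro"`, `"micro"`, `"unknown"`.
#' @param modality one of `"ultrasound"`, `"plethysmography"`,
#'   `"laser_doppler"`, `"other"`, `"unknown"`.
#' @param bio_category one of `"exercise"`, `"supplement_diet"`,
#'   `"pathophysiology"`, `"other"`, `"unknown"`.
#' @param is_duplicate logical flag marking records coded as duplicates.
#' @return A `data.frame` of class `effects_df` with one row per record,
#'   validated against the schema invariants.
#' @examples
#' effect_records(es_value = c(0.4, -1.1), es_metric = "cohens_d",
#'                meta_id = c("M1", "M2"))
#' @export
effect_records <- function(es_value, es_metric, meta_id,
                           record_id = NULL,
                           ci_lower = NA_real_, ci_upper = NA_real_,
                           n_treatment = NA_integer_, n_control = NA_integer_,
                           year = NA_integer_,
                           vessel_bed = "unknown", modality = "unknown",
                           bio_category = "unknown", is_duplicate = FALSE) {
  n <- length(es_value)
  if (is.null(record_id)) record_id <- sprintf("E%04d", seq_len(n))
  df <- data.frame(
    record_id = as.character(record_id),
    meta_id = as.character(rep_len(meta_id, n)),
    es_value = as.numeric(es_value),
    es_metric = rep_len(as.character(es_metric), n),
    ci_lower = rep_len(as.numeric(ci_lower), n),
    ci_upper = rep_len(as.numeric(ci_upper), n),
    n_treatment = rep_len(as.integer(n_treatment), n),
    n_control = rep_len(as.integer(n_control), n),
    year = rep_len(as.integer(year), n),
    vessel_bed = rep_len(as.character(vessel_bed), n),
    modality = rep_len(as.character(modality), n),
    bio_category = rep_len(as.character(bio_category), n),
    is_duplicate = rep_len(as.logical(is_duplicate), n),
    stringsAsFactors = FALSE
  )
  validate_effects(df)
}

#' Validate an effects table against the schema invariants
#'
#' Checks enum membership, positivity of sample sizes and the CI ordering
#' `ci_lower <= es_value <= ci_upper` wherever both bounds are present.
#' Errors cite the offending row index.
#'
#' @param df a data.frame with at least the required columns
#'   `es_value`, `es_metric`, `meta_id`.
#' @return `df`, classed as `effects_df`, invisibly usable downstream.
#' @export
validate_effects <- function(df) {
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  chk_enum <- function(col, vocab) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% vocab))
    if (length(bad) > 0)
      stop(sprintf("row %d: invalid %s value %s (expected one of: %s)",
                   bad[1], col, dQuote(df[[col]][bad[1]]),
                   paste(vocab, collapse = ", ")), call. = FALSE)
  }
  bad_na <- which(is.na(df$es_value))
  if (length(bad_na) > 0)
    stop(sprintf("row %d: es_value is missing or non-numeric", bad_na[1]),
         call. = FALSE)
  chk_enum("es_metric", .es_metrics)
  bad_metric_na <- which(is.na(df$es_metric))
  if (length(bad_metric_na) > 0)
    stop(sprintf("row %d: es_metric is missing", bad_metric_na[1]),
         call. = FALSE)
  if ("vessel_bed" %in% names(df)) chk_enum("vessel_bed", .vessel_beds)
  if ("modality" %in% names(df)) chk_enum("modality", .modalities)
  if ("bio_category" %in% names(df)) chk_enum("bio_category", .bio_categories)
  for (col in c("n_treatment", "n_control")) {
    if (!col %in% names(df)) next
    bad <- which(!is.na(df[[col]]) & df[[col]] < 1)
    if (length(bad) > 0)
      stop(sprintf("row %d: %s must be >= 1", bad[1], col), call. = FALSE)
  }
  if (all(c("ci_lower", "ci_upper") %in% names(df))) {
    both <- !is.na(df$ci_lower) & !is.na(df$ci_upper)
    bad <- which(both & !(df$ci_lower <= df$es_value &
                          df$es_value <= df$ci_upper))
    if (length(bad) > 0)
      stop(sprintf("row %d: ci bounds do not bracket es_value", bad[1]),
           call. = FALSE)
  }
  class(df) <- unique(c("effects_df", class(df)))
  df
}

#' Read an effects table from CSV
#'
#' The expected dialect is UTF-8, comma-separated, with a header row; empty
#' cells are missing values. Required columns: `es_value`, `es_metric`,
#' `meta_id`. Optional columns absent from the file are filled with default
#' missing/unknown values. Input row order is preserved.
#'
#' @param path path to a CSV file.
#' @return a validated `effects_df` (see [effect_records()]).
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8",
                         na.strings = c("", "NA"),
                         colClasses = "character")
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0)
      stop(sprintf("row %d: unparseable numeric in column %s: %s",
                   bad[1], col, dQuote(raw[[col]][bad[1]])), call. = FALSE)
    v
  }
  chr <- function(col, default) {
    if (!col %in% names(raw)) return(rep(default, nrow(raw)))
    v <- raw[[col]]
    v[is.na(v)] <- default
    v
  }
  lgl <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    v <- toupper(trimws(raw[[col]]))
    out <- v %in% c("TRUE", "T", "1", "YES")
    out
  }
  effect_records(
    es_value = num("es_value"),
    es_metric = raw$es_metric,
    meta_id = raw$meta_id,
    record_id = if ("record_id" %in% names(raw)) raw$record_id else NULL,
    ci_lower = num("ci_lower"), ci_upper = num("ci_upper"),
    n_treatment = as.integer(num("n_treatment")),
    n_control = as.integer(num("n_control")),
    year = as.integer(num("year")),
    vessel_bed = chr("vessel_bed", "unknown"),
    modality = chr("modality", "unknown"),
    bio_category = chr("bio_category", "unknown"),
    is_duplicate = lgl("is_duplicate")
  )
}

#' Write an effects table to CSV
#'
#' @param records an `effects_df`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_effects <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Apply the cleaning rules: drop duplicates, then outliers
#'
#' Removes first every record flagged `is_duplicate`, then every record whose
#' absolute effect value strictly exceeds `outlier_threshold` (default 8, the
#' magnitude beyond which extracted SMDs are deemed unrealistically large).
#' The threshold applies to the value on its reported metric, before any
#' d/g conversion. Survivor order is preserved and removal counts satisfy
#' the conservation law `n_input = retained + duplicates + outliers`.
#'
#' @param records an `effects_df`.
#' @param outlier_threshold positive magnitude; strict `|es| >` rule.
#' @param auto_detect_duplicates if `TRUE`, additionally flags later exact
#'   repeats of the tuple (es_value, ci_lower, ci_upper, n_treatment,
#'   n_control) as duplicates before removal. Off by default: duplicate
#'   handling is flag-driven.
#' @return an object of class `clean_result`: a list with elements
#'   `retained` (an `effects_df`), `n_input`, `n_duplicates_removed`,
#'   `n_outliers_removed`.
#' @examples
#' rec <- effect_records(es_value = c(0.4, 0.4, 9.2, -0.7, 1.0),
#'                       es_metric = "cohens_d", meta_id = "M1",
#'                       is_duplicate = c(FALSE, TRUE, FALSE, FALSE, FALSE))
#' clean_effects(rec)
#' @export
clean_effects <- function(records, outlier_threshold = 8,
                          auto_detect_duplicates = FALSE) {
  if (!is.numeric(outlier_threshold) || length(outlier_threshold) != 1 ||
      is.na(outlier_threshold) || outlier_threshold <= 0)
    stop("outlier_threshold must be a positive number", call. = FALSE)
  records <- validate_effects(as.data.frame(records))
  n_input <- nrow(records)
  dup <- records$is_duplicate
  if (auto_detect_duplicates && n_input > 0) {
    key <- paste(records$es_value, records$ci_lower, records$ci_upper,
                 records$n_treatment, records$n_control, sep = "\r")
    dup <- dup | duplicated(key)
  }
  after_dup <- records[!dup, , drop = FALSE]
  out <- abs(after_dup$es_value) > outlier_threshold
  retained <- after_dup[!out, , drop = FALSE]
  rownames(retained) <- NULL
  res <- list(
    retained = validate_effects(retained),
    n_input = n_input,
    n_duplicates_removed = sum(dup),
    n_outliers_removed = sum(out),
    outlier_threshold = outlier_threshold
  )
  class(res) <- "clean_result"
  res
}

#' @export
print.clean_result <- function(x, ...) {
  cat("Effect-size cleaning audit\n")
  cat(sprintf("  input records:      %d\n", x$n_input))
  cat(sprintf("  duplicates removed: %d\n", x$n_duplicates_removed))
  cat(sprintf("  outliers removed:   %d (|es| > %g)\n",
              x$n_outliers_removed, x$outlier_threshold))
  cat(sprintf("  retained:           %d\n", nrow(x$retained)))
  invisible(x)
}

#' Write the cleaning audit as JSON
#'
#' @param result a `clean_result`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cleaning_audit <- function(result, path) {
  stopifnot(inherits(result, "clean_result"))
  jsonlite::write_json(
    list(n_input = result$n_input,
         n_duplicates_removed = result$n_duplicates_removed,
         n_outliers_removed = result$n_outliers_removed,
         n_retained = nrow(result$retained),
         outlier_threshold = result$outlier_threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Absolute effect-size magnitudes
#'
#' The benchmark analysis concerns the magnitude, not the direction, of
#' reported effects; this returns element-wise `|es_value|` in input order.
#'
#' @param records an `effects_df`, or a bare numeric vector of effect values.
#' @return numeric vector of non-negative magnitudes.
#' @export
magnitudes <- function(records) {
  if (is.numeric(records)) return(abs(records))
  abs(records$es_value)
}
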