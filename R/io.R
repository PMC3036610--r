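#' Cohort CSV schema
#'
#' The documented column schema for cohort CSV files (UTF-8, comma separator,
#' `.` decimal, mandatory header). Shipped as
#' `inst/extdata/cohort-schema.csv` as well.
#'
#' @return tibble with `column`, `type`, `unit`, `required`.
#' @examples
#' cohort_schema()
#' @export
cohort_schema <- function() {
  tibble::tribble(
    ~column, ~type, ~unit, ~required,
    "subject_id", "character", "", FALSE,
    "group", "factor", "control|ms_only|t2dm_only|t2dm_ms", TRUE,
    "ethnicity", "factor", "malay|chinese|indian", TRUE,
    "age", "numeric", "years", TRUE,
    "bmi", "numeric", "kg/m2", FALSE,
    "waist", "numeric", "cm", FALSE,
    "whr", "numeric", "ratio", FALSE,
    "sbp", "numeric", "mmHg", FALSE,
    "dbp", "numeric", "mmHg", FALSE,
    "total_chol", "numeric", "mmol/L", FALSE,
    "hdl", "numeric", "mmol/L", FALSE,
    "ldl", "numeric", "mmol/L", FALSE,
    "tg", "numeric", "mmol/L", FALSE,
    "glucose", "numeric", "mmol/L", TRUE,
    "hba1c", "numeric", "%", FALSE,
    "insulin", "numeric", "uU/mL", TRUE,
    "adiponectin", "numeric", "ug/mL", TRUE,
    "resistin", "numeric", "ng/mL", TRUE,
    "smoking", "logical", "", FALSE,
    "hypertension", "logical", "", FALSE,
    "family_history", "logical", "", FALSE
  )
}

#' Write a cohort to CSV with a JSON metadata sidecar
#'
#' @param data cohort tibble (as from [generate_cohort()]).
#' @param path output CSV path; the metadata sidecar is written to
#'   `paste0(path, ".json")` unless `metadata_path` is given.
#' @param metadata_path optional sidecar path, `NA` to skip metadata.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, metadata_path = paste0(path, ".json")) {
  readr::write_csv(data, path)
  if (!is.na(metadata_path)) {
    meta <- list(
      package = "arindex",
      package_version = as.character(packageVersion("arindex")),
      seed = attr(data, "seed"),
      scale = attr(data, "scale"),
      n_rows = nrow(data),
      columns = names(data)
    )
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Units are interpreted per [cohort_schema()] (glucose mmol/L, insulin
#' uU/mL, adiponectin ug/mL, resistin ng/mL). Rows violating the record
#' invariants (non-positive biomarkers, age outside \[40, 70\],
#' `hdl >= total_chol`) are rejected with row-numbered warnings; structural
#' problems (missing required columns, non-numeric cells, empty file) are
#' errors.
#'
#' @param path CSV file path.
#' @param validate reject invalid rows (default `TRUE`).
#' @return validated cohort tibble.
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "arindex_io_error")
  }
  schema <- cohort_schema()
  data <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols())
  if (nrow(data) == 0L) {
    abort("Empty cohort file.", class = "arindex_io_error")
  }
  missing_cols <- setdiff(schema$column[schema$required], names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "arindex_schema_error")
  }
  numeric_cols <- intersect(schema$column[schema$type == "numeric"], names(data))
  for (col in numeric_cols) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("Column `%s` must be numeric.", col),
            class = "arindex_schema_error")
    }
  }
  data$group <- factor(data$group,
                       levels = intersect(group_levels, unique(data$group)))
  data$ethnicity <- factor(data$ethnicity,
                           levels = intersect(ethnicity_levels,
                                              unique(data$ethnicity)))
  if (validate) {
    bad <- rep(FALSE, nrow(data))
    flag <- function(cond, field, why) {
      cond[is.na(cond)] <- FALSE
      if (any(cond)) {
        warn(sprintf("Rejecting row(s) %s: %s %s.",
                     paste(head(which(cond), 10L), collapse = ", "),
                     field, why))
      }
      cond
    }
    positive_cols <- intersect(
      c("bmi", "waist", "whr", "sbp", "dbp", "total_chol", "hdl", "ldl",
        "tg", "glucose", "hba1c", "insulin", "adiponectin", "resistin"),
      names(data)
    )
    for (col in positive_cols) {
      bad <- bad | flag(data[[col]] <= 0, col, "must be strictly positive")
    }
    bad <- bad | flag(data$age < 40 | data$age > 70, "age",
                      "must lie in [40, 70]")
    if (all(c("hdl", "total_chol") %in% names(data))) {
      bad <- bad | flag(data$hdl >= data$total_chol, "hdl",
                        "must be below total_chol")
    }
    data <- data[!bad, , drop = FALSE]
    if (nrow(data) == 0L) {
      abort("All rows rejected by validation.", class = "arindex_schema_error")
    }
  }
  tibble::as_tibble(data)
}

#' Read a run configuration file (YAML or JSON)
#'
#' Recognised fields: `replicates` (>= 100, default 1000), `level`
#' (in (0.5, 1), default 0.95), `seed`, `scale`, `dialect` (arguments to
#' [formula_dialect()]) and `thresholds` (arguments to [risk_thresholds()]).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return list of class `run_config` with `dialect` and `thresholds`
#'   realised as objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "arindex_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- modifyList(
    list(replicates = 1000L, level = 0.95, seed = NULL, scale = 1,
         dialect = list(), thresholds = list()),
    as.list(raw)
  )
  if (cfg$replicates < 100) {
    abort("`replicates` must be at least 100.", class = "arindex_config_error")
  }
  if (cfg$level <= 0.5 || cfg$level >= 1) {
    abort("`level` must lie in (0.5, 1).", class = "arindex_config_error")
  }
  cfg$dialect <- do.call(formula_dialect, cfg$dialect)
  cfg$thresholds <- do.call(risk_thresholds, cfg$thresholds)
  structure(cfg, class = "run_config")
}

#' Write the evaluation report as CSV tables plus a JSON summary
#'
#' One CSV per analysis table (omnibus ANCOVA with flattened pairwise
#' contrasts, group summaries, MANCOVA, the two correlation tables, band
#' counts) and `summary.json` carrying the run metadata.
#'
#' @param evaluation an [evaluate_case_control()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "ar_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairwise <- evaluation$comparisons |>
    dplyr::select("variable", "pairwise") |>
    tidyr::unnest("pairwise")
  readr::write_csv(tidy(evaluation), file.path(dir, "ancova_omnibus.csv"))
  readr::write_csv(pairwise, file.path(dir, "pairwise_contrasts.csv"))
  readr::write_csv(evaluation$group_summary, file.path(dir, "group_summary.csv"))
  readr::write_csv(evaluation$mancova$table, file.path(dir, "mancova.csv"))
  readr::write_csv(evaluation$correlations_clinical,
                   file.path(dir, "correlations_clinical.csv"))
  readr::write_csv(evaluation$correlations_indices,
                   file.path(dir, "correlations_indices.csv"))
  readr::write_csv(evaluation$band_counts, file.path(dir, "band_counts.csv"))
  jsonlite::write_json(evaluation$meta, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
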