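evaluation_variable_sets <- function() {
  list(
    anthropometric = c("bmi", "waist", "whr", "sbp", "dbp"),
    metabolic = c("total_chol", "hdl", "ldl", "tg", "glucose", "hba1c",
                  "insulin"),
    adipokine = c("adiponectin", "resistin"),
    index = c("ar", "homa_ir", "quicki", "bennett", "mcauley_tg",
              "mcauley_ins", "ir_ar")
  )
}

#' Run the full case-control evaluation
#'
#' Orchestrates the whole analysis on a four-group cohort: computes the seven
#' index columns and risk bands, runs the age-adjusted ANCOVA omnibus test
#' plus stratified BCa pairwise contrasts for every anthropometric, metabolic,
#' adipokine and index variable, the MANCOVA for the joint
#' adiponectin-resistin response, and the Spearman correlation tables of the
#' clinical variables and surrogate indexes against adiponectin, resistin and
#' the AR index. Group summaries carry both raw means with t-based 95% CIs
#' and ANCOVA-adjusted means, labelled. Deterministic given `seed` (one RNG
#' stream for all bootstrap work).
#'
#' @param cohort data frame of subject records (see [generate_cohort()] /
#'   [read_cohort()] for the schema); must contain all four groups.
#' @param dialect a [formula_dialect()].
#' @param thresholds a [risk_thresholds()].
#' @param replicates bootstrap replicates per pairwise contrast.
#' @param level confidence level for pairwise intervals.
#' @param seed integer seed.
#' @param variables optional character vector restricting the per-variable
#'   comparisons (defaults to the full study layout).
#' @return object of class `ar_evaluation`: `$indexed` (cohort with index and
#'   band columns), `$comparisons` (omnibus tibble with a `pairwise` list
#'   column), `$group_summary`, `$mancova`, `$correlations_clinical`,
#'   `$correlations_indices`, `$band_counts`, `$meta`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' ev <- evaluate_case_control(cohort, replicates = 200, seed = 2,
#'                             variables = c("insulin", "ar"))
#' tidy(ev)
#' @export
evaluate_case_control <- function(cohort,
                                  dialect = formula_dialect(),
                                  thresholds = risk_thresholds(),
                                  replicates = 1000,
                                  level = 0.95,
                                  seed = NULL,
                                  variables = NULL) {
  if (replicates < 100) {
    abort("`replicates` must be at least 100.", class = "arindex_domain_error")
  }
  if (level <= 0.5 || level >= 1) {
    abort("`level` must lie in (0.5, 1).", class = "arindex_domain_error")
  }
  check_column(cohort, "group", "evaluate_case_control")
  g <- as.factor(cohort$group)
  if (nlevels(droplevels(g)) < 4L) {
    abort("The case-control evaluation needs all four groups.",
          class = "arindex_domain_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  indexed <- classify_cohort(compute_indices(cohort, dialect), thresholds)
  sets <- evaluation_variable_sets()
  vars <- variables %||% unlist(sets, use.names = FALSE)
  vars <- intersect(vars, names(indexed))

  comparisons <- purrr::map_dfr(vars, function(v) {
    omnibus <- ancova_group_test(indexed, v)
    pw <- pairwise_group_contrasts(indexed, v, replicates = replicates,
                                   level = level)
    tibble::tibble(
      variable = v,
      df_hypothesis = omnibus$df_hypothesis,
      df_error = omnibus$df_error,
      f_statistic = omnibus$f_statistic,
      p_value = omnibus$p_value,
      pairwise = list(pw),
      adjusted_means = list(omnibus$adjusted_means)
    )
  })

  group_summary <- indexed |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(.data$variable, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      ci_low = mean(.data$value) -
        stats::qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n()),
      ci_high = mean(.data$value) +
        stats::qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      comparisons |>
        dplyr::select("variable", "adjusted_means") |>
        tidyr::unnest("adjusted_means"),
      by = c("variable", "group")
    )

  mancova <- mancova_group_test(indexed)

  clinical_vars <- c("age", sets$anthropometric, sets$metabolic)
  correlations_clinical <- correlation_table(indexed, clinical_vars)
  correlations_indices <- correlation_table(
    indexed, c("homa_ir", "quicki", "bennett", "mcauley_tg", "mcauley_ins")
  )

  band_counts <- indexed |>
    dplyr::count(.data$group, .data$ar_band, .data$irar_band)

  structure(
    list(
      indexed = indexed,
      comparisons = comparisons |> dplyr::select(-"adjusted_means"),
      group_summary = group_summary,
      mancova = mancova,
      correlations_clinical = correlations_clinical,
      correlations_indices = correlations_indices,
      band_counts = band_counts,
      meta = list(seed = seed, replicates = replicates, level = level,
                  n = nrow(cohort),
                  package_version = as.character(packageVersion("arindex")))
    ),
    class = "ar_evaluation"
  )
}

#' @export
print.ar_evaluation <- function(x, ...) {
  cat(sprintf(
    "<ar_evaluation> n = %d subjects, %d variables compared, B = %d bootstrap replicates\n",
    x$meta$n, nrow(x$comparisons), x$meta$replicates
  ))
  cat("Omnibus ANCOVA (group factor, age-adjusted):\n")
  print(x$comparisons |> dplyr::select(-"pairwise"), n = Inf)
  cat("MANCOVA (adiponectin + resistin):\n")
  print(x$mancova$table)
  invisible(x)
}

#' @method tidy ar_evaluation
#' @export
tidy.ar_evaluation <- function(x, ...) {
  x$comparisons |> dplyr::select(-"pairwise")
}

#' @method glance ar_evaluation
#' @export
glance.ar_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$meta$n,
    n_variables = nrow(x$comparisons),
    replicates = x$meta$replicates,
    level = x$meta$level,
    seed = x$meta$seed %||% NA_integer_
  )
}
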