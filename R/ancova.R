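#' Age-adjusted ANCOVA omnibus test for a group difference
#'
#' Fits the general linear model `variable ~ group + covariate` (each subject
#' group a fixed factor, age the covariate) and reports the Type III F test
#' for the group factor. With no interaction terms this marginal test equals
#' the full-versus-reduced-model F computed from residual sums of squares,
#' a property the test suite checks against an explicit least-squares oracle.
#'
#' @param data data frame with the response, group and covariate columns.
#' @param variable response column name (string).
#' @param covariate covariate column name (default `"age"`).
#' @param group grouping column name (default `"group"`); coerced to factor.
#' @return object of class `ar_ancova` with the omnibus F, degrees of
#'   freedom, p-value, the fitted model, and age-adjusted group means
#'   (predictions at the mean covariate, with t-based 95% CIs).
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' ancova_group_test(cohort, "insulin")
#' @export
ancova_group_test <- function(data, variable, covariate = "age",
                              group = "group") {
  for (col in c(variable, covariate, group)) {
    check_column(data, col, "ancova_group_test")
  }
  d <- data.frame(
    y = as.numeric(data[[variable]]),
    g = droplevels(as.factor(data[[group]])),
    cov = as.numeric(data[[covariate]])
  )
  if (anyNA(d)) {
    abort("Response and covariate must be complete (no missing values).",
          class = "arindex_domain_error")
  }
  if (nlevels(d$g) < 2L || any(table(d$g) < 3L)) {
    abort("Need at least 2 groups with at least 3 subjects each.",
          class = "arindex_domain_error")
  }
  fit <- lm(y ~ g + cov, data = d, contrasts = list(g = "contr.sum"))
  if (anyNA(coef(fit))) {
    abort(
      paste0("Rank-deficient design; aliased terms: ",
             paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
      class = "arindex_domain_error"
    )
  }
  a3 <- car::Anova(fit, type = 3)
  grow <- a3["g", ]
  df_err <- a3["Residuals", "Df"]
  newd <- data.frame(g = factor(levels(d$g), levels = levels(d$g)),
                     cov = mean(d$cov))
  pr <- stats::predict(fit, newdata = newd, se.fit = TRUE)
  tcrit <- stats::qt(0.975, df_err)
  adjusted <- tibble::tibble(
    group = levels(d$g),
    adj_mean = as.numeric(pr$fit),
    adj_ci_low = as.numeric(pr$fit - tcrit * pr$se.fit),
    adj_ci_high = as.numeric(pr$fit + tcrit * pr$se.fit)
  )
  structure(
    list(variable = variable, covariate = covariate,
         df_hypothesis = grow[["Df"]], df_error = df_err,
         f_statistic = grow[["F value"]], p_value = grow[["Pr(>F)"]],
         n = nrow(d), adjusted_means = adjusted, model = fit),
    class = "ar_ancova"
  )
}

#' @export
print.ar_ancova <- function(x, ...) {
  cat(sprintf(
    "<ar_ancova> %s ~ group + %s: F(%d, %d) = %.3f, p = %.3g (n = %d)\n",
    x$variable, x$covariate, x$df_hypothesis, x$df_error,
    x$f_statistic, x$p_value, x$n
  ))
  invisible(x)
}

#' @method tidy ar_ancova
#' @export
tidy.ar_ancova <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, df_hypothesis = x$df_hypothesis,
    df_error = x$df_error, statistic = x$f_statistic, p_value = x$p_value
  )
}

#' @method glance ar_ancova
#' @export
glance.ar_ancova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    n = x$n, r_squared = s$r.squared, statistic = x$f_statistic,
    p_value = x$p_value, df_hypothesis = x$df_hypothesis,
    df_error = x$df_error
  )
}

#' Pairwise group contrasts with stratified BCa bootstrap intervals
#'
#' For every pair of group levels, the difference in group means is
#' bootstrapped by resampling with replacement within each group-by-stratum
#' cell (cell sizes preserved) and summarised by BCa intervals. Significance
#' grades follow the nested-interval convention: `*` when the 95% interval
#' excludes zero, `**` at 99%, `***` at 99.9%.
#'
#' @inheritParams ancova_group_test
#' @param strata stratification column (default `"ethnicity"`); every stratum
#'   level must be populated in both groups of a contrast.
#' @param replicates bootstrap replicates per contrast (default 1000).
#' @param level confidence level of the reported interval.
#' @param seed integer seed for the whole set of contrasts (single RNG
#'   stream, pairs processed in level order).
#' @return tibble with one row per pair: `group_i`, `group_j`,
#'   `mean_difference` (mean of `group_i` minus mean of `group_j`),
#'   `conf_low`, `conf_high`, `z0`, `acceleration`, `grade`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' pairwise_group_contrasts(cohort, "insulin", replicates = 200, seed = 2)
#' @export
pairwise_group_contrasts <- function(data, variable, group = "group",
                                     strata = "ethnicity", replicates = 1000,
                                     level = 0.95, seed = NULL) {
  for (col in c(variable, group, strata)) {
    check_column(data, col, "pairwise_group_contrasts")
  }
  g <- droplevels(as.factor(data[[group]]))
  s <- as.factor(data[[strata]])
  y <- as.numeric(data[[variable]])
  lev <- levels(g)
  if (length(lev) < 2L) {
    abort("Need at least two groups.", class = "arindex_domain_error")
  }
  cell <- table(g, droplevels(s))
  if (any(cell == 0L)) {
    abort("Empty stratum: every group must contain every stratum level.",
          class = "arindex_domain_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  pairs <- utils::combn(lev, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    gi <- pairs[1, k]; gj <- pairs[2, k]
    sel_i <- g == gi; sel_j <- g == gj
    res <- bca_mean_diff(y[sel_i], as.character(s[sel_i]),
                         y[sel_j], as.character(s[sel_j]),
                         replicates = replicates, level = level)
    tibble::tibble(
      group_i = gi, group_j = gj, mean_difference = res$estimate,
      conf_low = res$conf_low, conf_high = res$conf_high,
      z0 = res$z0, acceleration = res$acceleration, grade = res$grade
    )
  })
}

#' Omnibus plus pairwise comparison of groups for one variable
#'
#' Bundles the age-adjusted ANCOVA omnibus test and the stratified BCa
#' pairwise contrasts into one result.
#'
#' @inheritParams pairwise_group_contrasts
#' @inheritParams ancova_group_test
#' @return object of class `ar_group_comparison`: the `ar_ancova` omnibus
#'   fit under `$omnibus` and the pairwise tibble under `$pairwise`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' cmp <- group_comparison(cohort, "insulin", replicates = 200, seed = 2)
#' tidy(cmp)
#' @export
group_comparison <- function(data, variable, covariate = "age",
                             group = "group", strata = "ethnicity",
                             replicates = 1000, level = 0.95, seed = NULL) {
  omnibus <- ancova_group_test(data, variable, covariate, group)
  pairwise <- pairwise_group_contrasts(data, variable, group, strata,
                                       replicates, level, seed)
  structure(
    list(variable = variable, omnibus = omnibus, pairwise = pairwise),
    class = "ar_group_comparison"
  )
}

#' @export
print.ar_group_comparison <- function(x, ...) {
  print(x$omnibus)
  print(x$pairwise)
  invisible(x)
}

#' @method tidy ar_group_comparison
#' @export
tidy.ar_group_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x$omnibus)[rep(1, nrow(x$pairwise)), ],
    x$pairwise
  )
}
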