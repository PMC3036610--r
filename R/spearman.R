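#' Spearman rank correlation matrix with two-tailed p-values
#'
#' Rank correlation with average ranks for ties: rho is the Pearson
#' correlation of the ranks, and the two-tailed p-value uses the t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees
#' of freedom (the nonparametric choice because most biomarkers here are not
#' normally distributed). Constant variables yield `NA` correlations with a
#' warning.
#'
#' @param data data frame.
#' @param variables character vector of (numeric) column names; at least 3
#'   complete rows are required.
#' @return object of class `ar_corr` with symmetric `$rho` and `$p_value`
#'   matrices and the sample size `$n`. `tidy()` flattens to the
#'   lower-triangle long form.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' sp <- spearman_matrix(cohort, c("adiponectin", "resistin", "insulin"))
#' tidy(sp)
#' @export
spearman_matrix <- function(data, variables) {
  for (col in variables) check_column(data, col, "spearman_matrix")
  X <- as.matrix(data[variables])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 3L) {
    abort("Need at least 3 complete rows.", class = "arindex_domain_error")
  }
  constant <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    warn(paste0("Constant variable(s), correlations undefined: ",
                paste(variables[constant], collapse = ", ")))
  }
  ranks <- apply(X, 2, rank)
  ranks[, constant] <- NA_real_
  rho <- suppressWarnings(cor(ranks))
  diag(rho) <- ifelse(constant, NA_real_, 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  p[is.na(rho)] <- NA_real_
  structure(
    list(rho = rho, p_value = p, n = n, variables = variables),
    class = "ar_corr"
  )
}

#' @export
print.ar_corr <- function(x, digits = 4, ...) {
  cat(sprintf("<ar_corr> Spearman rho over %d variables (n = %d)\n",
              length(x$variables), x$n))
  print(round(x$rho, digits))
  invisible(x)
}

#' @method tidy ar_corr
#' @export
tidy.ar_corr <- function(x, ...) {
  v <- x$variables
  pairs <- which(lower.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = v[pairs[, "col"]],
    var2 = v[pairs[, "row"]],
    rho = x$rho[pairs],
    p_value = x$p_value[pairs],
    n = x$n
  )
}

#' Correlation of a set of variables against reference columns
#'
#' Long-form helper reproducing the layout of the published correlation
#' tables: each `row_vars` variable correlated against each of `col_vars`
#' (typically adiponectin, resistin and the AR index).
#'
#' @param data data frame (indexed cohort).
#' @param row_vars variables forming the table rows.
#' @param col_vars variables forming the table columns.
#' @return tibble with `variable`, `against`, `rho`, `p_value`, `n`.
#' @examples
#' cohort <- compute_indices(generate_cohort(default_cohort_spec(0.1), seed = 1))
#' correlation_table(cohort, c("glucose", "insulin"),
#'                   c("adiponectin", "resistin", "ar"))
#' @export
correlation_table <- function(data, row_vars,
                              col_vars = c("adiponectin", "resistin", "ar")) {
  sp <- spearman_matrix(data, unique(c(row_vars, col_vars)))
  purrr::map_dfr(row_vars, function(rv) {
    tibble::tibble(
      variable = rv,
      against = setdiff(col_vars, rv),
      rho = sp$rho[rv, setdiff(col_vars, rv)],
      p_value = sp$p_value[rv, setdiff(col_vars, rv)],
      n = sp$n
    )
  })
}
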