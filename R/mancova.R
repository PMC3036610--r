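#' Multivariate test statistics from eigenvalues
#'
#' The four classical MANOVA/MANCOVA statistics are all functions of the
#' eigenvalues \eqn{\lambda_i} of \eqn{E^{-1}H}: Pillai's trace
#' \eqn{\sum \lambda_i/(1+\lambda_i)}, Wilks' lambda
#' \eqn{\prod 1/(1+\lambda_i)}, Hotelling's trace \eqn{\sum \lambda_i} and
#' Roy's largest root \eqn{\max \lambda_i}.
#'
#' @param eigenvalues nonnegative eigenvalues of \eqn{E^{-1}H}.
#' @return tibble with columns `statistic` and `value`.
#' @examples
#' mv_stats_from_eigen(c(0.219, 0.022))
#' @export
mv_stats_from_eigen <- function(eigenvalues) {
  if (any(eigenvalues < 0)) {
    abort("Eigenvalues of E^-1 H must be nonnegative.",
          class = "arindex_domain_error")
  }
  tibble::tibble(
    statistic = c("pillai", "wilks", "hotelling", "roy"),
    value = c(
      sum(eigenvalues / (1 + eigenvalues)),
      prod(1 / (1 + eigenvalues)),
      sum(eigenvalues),
      max(eigenvalues)
    )
  )
}

# standard F approximations; p = #responses, q = hypothesis df, v = error df
mv_f_approx <- function(stats_tbl, eigenvalues, p, q, v) {
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  np <- (v - p - 1) / 2
  val <- setNames(stats_tbl$value, stats_tbl$statistic)

  # Pillai
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * np + s + 1)
  f_p <- (df2_p / df1_p) * val["pillai"] / (s - val["pillai"])

  # Wilks (Rao's F)
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1_w <- p * q
  df2_w <- w * tt - (p * q - 2) / 2
  lam_t <- val["wilks"]^(1 / tt)
  f_w <- ((1 - lam_t) / lam_t) * df2_w / df1_w

  # Hotelling
  df1_h <- s * (2 * m + s + 1)
  df2_h <- 2 * (s * np + 1)
  f_h <- val["hotelling"] * df2_h / (s * df1_h)

  # Roy (upper bound)
  r <- max(p, q)
  df1_r <- r
  df2_r <- v - r + q
  f_r <- val["roy"] * df2_r / df1_r

  tibble::tibble(
    statistic = stats_tbl$statistic,
    value = stats_tbl$value,
    f = unname(c(f_p, f_w, f_h, f_r)),
    df1 = c(df1_p, df1_w, df1_h, df1_r),
    df2 = c(df2_p, df2_w, df2_h, df2_r),
    p_value = pf(unname(c(f_p, f_w, f_h, f_r)),
                 c(df1_p, df1_w, df1_h, df1_r),
                 c(df2_p, df2_w, df2_h, df2_r), lower.tail = FALSE)
  )
}

#' Age-adjusted MANCOVA for the joint adipokine response
#'
#' Fits the multivariate general linear model
#' `cbind(responses) ~ group + covariate`, forms the hypothesis (H) and error
#' (E) cross-product matrices for the group factor adjusted for the covariate
#' (Type III: H is the increase in the residual cross-product when the group
#' factor is dropped), extracts the eigenvalues of \eqn{E^{-1}H}, and reports
#' Pillai's trace, Wilks' lambda, Hotelling's trace and Roy's largest root
#' with their standard F approximations.
#'
#' @param data data frame of subject records.
#' @param responses character vector of response columns
#'   (default `c("adiponectin", "resistin")`).
#' @param covariate covariate column (default `"age"`).
#' @param group grouping column (default `"group"`).
#' @return object of class `ar_mancova` with `$eigenvalues` and a `$table`
#'   tibble (`statistic`, `value`, `f`, `df1`, `df2`, `p_value`).
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 1)
#' mancova_group_test(cohort)
#' @export
mancova_group_test <- function(data, responses = c("adiponectin", "resistin"),
                               covariate = "age", group = "group") {
  for (col in c(responses, covariate, group)) {
    check_column(data, col, "mancova_group_test")
  }
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2L) {
    abort("Need at least two groups.", class = "arindex_domain_error")
  }
  Y <- as.matrix(data[responses])
  if (anyNA(Y) || anyNA(data[[covariate]])) {
    abort("Responses and covariate must be complete.",
          class = "arindex_domain_error")
  }
  d <- data.frame(g = g, cov = as.numeric(data[[covariate]]))
  Xf <- model.matrix(~ g + cov, d)
  Xr <- model.matrix(~ cov, d)
  rf <- stats::lm.fit(Xf, Y)$residuals
  rr <- stats::lm.fit(Xr, Y)$residuals
  E <- crossprod(rf)
  H <- crossprod(rr) - E
  Einv_H <- tryCatch(solve(E, H), error = function(e) {
    abort("Singular error cross-product matrix E.",
          class = "arindex_domain_error")
  })
  lam <- sort(Re(eigen(Einv_H, only.values = TRUE)$values), decreasing = TRUE)
  lam <- pmax(lam, 0)
  p <- length(responses)
  q <- nlevels(g) - 1L
  v <- nrow(Y) - qr(Xf)$rank
  lam <- lam[seq_len(min(p, q))]
  tab <- mv_f_approx(mv_stats_from_eigen(lam), lam, p, q, v)
  structure(
    list(eigenvalues = lam, table = tab, responses = responses,
         df_hypothesis = q, df_error = v, n = nrow(Y)),
    class = "ar_mancova"
  )
}

#' @export
print.ar_mancova <- function(x, ...) {
  cat(sprintf("<ar_mancova> %s ~ group (+covariate); eigenvalues: %s\n",
              paste(x$responses, collapse = " + "),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  print(x$table)
  invisible(x)
}

#' @method tidy ar_mancova
#' @export
tidy.ar_mancova <- function(x, ...) x$table

#' @method glance ar_mancova
#' @export
glance.ar_mancova <- function(x, ...) {
  tibble::tibble(
    n = x$n, df_hypothesis = x$df_hypothesis, df_error = x$df_error,
    n_eigenvalues = length(x$eigenvalues)
  )
}
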