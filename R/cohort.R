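#' Back-derive a standard deviation from a reported 95% confidence interval
#'
#' Group summaries are published as mean (95% CI); the generator needs SDs.
#' Assuming the usual normal-theory interval,
#' \eqn{SD = \sqrt{n}\,(CI_{hi} - CI_{lo}) / (2 \times 1.959964)}.
#' For right-skewed variables this symmetric-interval back-derivation is an
#' approximation; the log-normal marginals absorb the skew.
#'
#' @param mean reported mean (any unit).
#' @param ci_low,ci_high reported 95% CI bounds, same unit.
#' @param n sample size behind the interval (>= 2).
#' @return standard deviation, same unit as `mean`.
#' @examples
#' sd_from_ci(10.99, 10.05, 11.97, 208)
#' @export
sd_from_ci <- function(mean, ci_low, ci_high, n) {
  if (any(ci_high <= ci_low)) {
    abort("Degenerate interval: `ci_high` must exceed `ci_low`.",
          class = "arindex_domain_error")
  }
  if (any(n < 2)) {
    abort("`n` must be at least 2.", class = "arindex_domain_error")
  }
  sqrt(n) * (ci_high - ci_low) / (2 * 1.959964)
}

group_levels <- c("control", "ms_only", "t2dm_only", "t2dm_ms")
ethnicity_levels <- c("malay", "chinese", "indian")

# variables drawn through the Gaussian copula (order fixed: it defines the
# latent correlation matrix layout and the RNG draw order)
copula_vars <- c("insulin", "glucose", "adiponectin", "resistin")

# mean (95% CI) per group for every continuous variable of the study design,
# full-scale group sizes 208/174/171/256
study_variable_table <- function() {
  row <- function(variable, dist, a, b, c, d) {
    tibble::tibble(
      variable = variable, dist = dist, group = group_levels,
      mean = c(a[1], b[1], c[1], d[1]),
      ci_low = c(a[2], b[2], c[2], d[2]),
      ci_high = c(a[3], b[3], c[3], d[3])
    )
  }
  dplyr::bind_rows(
    row("age", "trunc_normal", c(55, 54, 56), c(54, 53, 55), c(55, 54, 56), c(53, 52, 54)),
    row("bmi", "lognormal", c(24.39, 23.92, 24.87), c(27.18, 26.69, 27.69),
        c(24.13, 23.60, 24.67), c(28.32, 27.84, 28.78)),
    row("waist", "lognormal", c(89, 88, 90), c(96, 95, 97), c(90, 88, 91), c(100, 99, 102)),
    row("whr", "lognormal", c(0.898, 0.891, 0.904), c(0.929, 0.921, 0.938),
        c(0.914, 0.907, 0.922), c(0.952, 0.946, 0.957)),
    row("sbp", "normal", c(133, 130, 135), c(143, 140, 145), c(129, 127, 131), c(136, 134, 138)),
    row("dbp", "normal", c(83, 81, 84), c(88, 87, 90), c(79, 78, 80), c(83, 81, 84)),
    row("total_chol", "lognormal", c(5.03, 4.91, 5.14), c(5.16, 5.03, 5.29),
        c(4.68, 4.52, 4.85), c(4.64, 4.50, 4.78)),
    row("hdl", "lognormal", c(1.28, 1.25, 1.31), c(1.07, 1.03, 1.10),
        c(1.26, 1.22, 1.29), c(1.04, 1.01, 1.07)),
    row("ldl", "lognormal", c(3.14, 3.03, 3.26), c(3.09, 2.95, 3.25),
        c(2.88, 2.73, 3.04), c(2.69, 2.57, 2.81)),
    row("tg", "lognormal", c(1.31, 1.25, 1.37), c(2.20, 2.07, 2.34),
        c(1.20, 1.12, 1.27), c(2.02, 1.89, 2.16)),
    row("glucose", "lognormal", c(5.13, 5.05, 5.23), c(5.51, 5.39, 5.63),
        c(8.04, 7.60, 8.50), c(8.26, 7.94, 8.60)),
    row("hba1c", "lognormal", c(5.63, 5.57, 5.69), c(5.82, 5.76, 5.89),
        c(8.07, 7.78, 8.36), c(8.09, 7.90, 8.28)),
    row("insulin", "lognormal", c(10.99, 10.05, 11.97), c(19.94, 16.95, 23.42),
        c(14.86, 12.76, 17.04), c(24.32, 20.85, 27.95))
  )
}

# Adipokine group means are not tabulated in the source study (shown as
# figures only). The defaults below are calibration targets fixed once:
# with the stated coefficients of variation, the log-normal-implied group
# mean AR indexes land mid-interval of the published AR bands
# (~1.163 / 1.31 / 1.47 / 1.62) and decline/rise monotonically across groups.
adipokine_targets <- function(n_full) {
  adipo_mean <- c(8.7, 6.9, 6.0, 5.2)    # ug/mL, cv 0.45
  resist_mean <- c(12.44, 13.89, 17.35, 21.29)  # ng/mL, cv 0.40
  half <- function(m, cv) 1.959964 * cv * m / sqrt(n_full)
  dplyr::bind_rows(
    tibble::tibble(
      variable = "adiponectin", dist = "lognormal", group = group_levels,
      mean = adipo_mean,
      ci_low = adipo_mean - half(adipo_mean, 0.45),
      ci_high = adipo_mean + half(adipo_mean, 0.45)
    ),
    tibble::tibble(
      variable = "resistin", dist = "lognormal", group = group_levels,
      mean = resist_mean,
      ci_low = resist_mean - half(resist_mean, 0.40),
      ci_high = resist_mean + half(resist_mean, 0.40)
    )
  )
}

# rank-correlation targets for the copula variables; signs follow the
# published full-cohort correlation structure (adiponectin negative with
# insulin/glucose/resistin, resistin positive with insulin/glucose)
default_spearman_targets <- function() {
  v <- copula_vars
  m <- diag(4)
  dimnames(m) <- list(v, v)
  set <- function(m, i, j, r) { m[i, j] <- r; m[j, i] <- r; m }
  m <- set(m, "insulin", "glucose", 0.25)
  m <- set(m, "insulin", "adiponectin", -0.2374)
  m <- set(m, "insulin", "resistin", 0.1598)
  m <- set(m, "glucose", "adiponectin", -0.1725)
  m <- set(m, "glucose", "resistin", 0.3077)
  m <- set(m, "adiponectin", "resistin", -0.1053)
  m
}

#' Default synthetic cohort specification
#'
#' Encodes the four-group case-control design: 208 controls, 174 MS without
#' T2DM, 171 T2DM without MS, 256 T2DM with MS (809 subjects in total), three
#' ethnic strata per group with the published counts, and every published
#' group mean and 95% CI for the anthropometric and metabolic variables.
#' Adipokine targets are calibration defaults (see the methods vignette).
#'
#' @param scale fraction of the full study size (default 1); scaled group
#'   sizes use round-half-up, ethnicity splits use largest-remainder so counts
#'   always sum to the group size. SD back-derivation always uses the
#'   full-scale n the published intervals were computed under.
#' @param spearman_targets optional rank-correlation matrix over
#'   `insulin, glucose, adiponectin, resistin` inducing the Gaussian copula;
#'   `NULL` draws them independently. The default carries the published sign
#'   structure (e.g. adiponectin-resistin -0.1053).
#' @return object of class `cohort_spec`.
#' @examples
#' default_cohort_spec()
#' default_cohort_spec(scale = 0.1)$groups
#' @export
default_cohort_spec <- function(scale = 1,
                                spearman_targets = default_spearman_targets()) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    abort("`scale` must be a single positive number.",
          class = "arindex_domain_error")
  }
  n_full <- c(208L, 174L, 171L, 256L)
  eth_full <- rbind(
    c(75, 73, 60), c(62, 54, 58), c(43, 62, 66), c(101, 75, 80)
  )
  n_scaled <- as.integer(round_half_up(n_full * scale))
  eth_scaled <- t(vapply(
    seq_along(group_levels),
    function(i) allocate_counts(eth_full[i, ], n_scaled[i]),
    integer(3)
  ))
  groups <- tibble::tibble(
    group = group_levels,
    n = n_scaled,
    malay = eth_scaled[, 1], chinese = eth_scaled[, 2], indian = eth_scaled[, 3],
    ci_n = n_full
  )
  variables <- dplyr::bind_rows(study_variable_table(), adipokine_targets(n_full))
  binary <- tibble::tibble(
    variable = rep(c("smoking", "hypertension", "family_history"), each = 4),
    group = rep(group_levels, 3),
    prob = c(39, 48, 55, 91, 0, 123, 13, 219, 0, 45, 107, 166) /
      rep(n_full, 3)
  )
  spec <- structure(
    list(groups = groups, variables = variables, binary = binary,
         spearman_targets = spearman_targets, scale = scale),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  g <- spec$groups
  if (any(g$malay + g$chinese + g$indian != g$n)) {
    abort("Ethnicity counts must sum to the group size.",
          class = "arindex_domain_error")
  }
  v <- spec$variables
  if (any(v$ci_low >= v$mean | v$mean >= v$ci_high)) {
    abort("Each variable needs ci_low < mean < ci_high.",
          class = "arindex_domain_error")
  }
  if (!is.null(spec$spearman_targets)) {
    latent <- latent_correlation(spec$spearman_targets)
    ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      abort("Infeasible correlation targets: latent matrix is not positive definite.",
            class = "arindex_domain_error")
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> scale =", x$scale, "| total n =", sum(x$groups$n), "\n")
  print(x$groups)
  invisible(x)
}

# Spearman rank target -> Pearson correlation of the latent normals
latent_correlation <- function(rs) 2 * sin(pi * rs / 6)

# location parameter of a normal truncated to [lo, hi] whose truncated mean
# equals `target`, given scale `sd`
trunc_normal_location <- function(target, sd, lo, hi) {
  f <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (pnorm(b) - pnorm(a)) - target
  }
  # bracket kept within ~3 sd of the bounds so the normalising mass cannot
  # underflow; the truncated mean is monotone in mu
  stats::uniroot(f, lower = lo - 3 * sd, upper = hi + 3 * sd,
                 tol = 1e-10)$root
}

draw_lognormal <- function(z, m, s) {
  sigma2 <- log(1 + (s / m)^2)
  exp(log(m) - sigma2 / 2 + sqrt(sigma2) * z)
}

#' Generate a synthetic subject-level cohort
#'
#' Draws one row per subject under the design in `spec`: exact group and
#' ethnicity counts; log-normal marginals (moment-matched to the target mean
#' and back-derived SD on the natural scale) for the positive right-skewed
#' biomarkers; a symmetric truncated normal on \[40, 70\] for age, with the
#' location solved so the truncated mean hits the target; normals for blood
#' pressures; a Gaussian copula over the latent normals of insulin, glucose,
#' adiponectin and resistin inducing the rank-correlation targets; and
#' group-wise Bernoulli draws for the binary covariates (smoking,
#' hypertension, family history of diabetes) carried for realism. Rows with
#' `hdl >= total_chol` are redrawn so every record satisfies the schema
#' invariants. Output is byte-identical for identical `(spec, seed)`.
#'
#' @param spec a [default_cohort_spec()] (or modified copy).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return tibble of subject records, one row per subject, with the seed (if
#'   any) recorded in the `"seed"` attribute.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(scale = 0.1), seed = 42)
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  if (!is.null(seed)) withr::local_seed(seed)

  latent_chol <- NULL
  if (!is.null(spec$spearman_targets)) {
    latent <- latent_correlation(spec$spearman_targets[copula_vars, copula_vars])
    diag(latent) <- 1
    latent_chol <- chol(latent)
  }

  out <- vector("list", nrow(spec$groups))
  for (i in seq_len(nrow(spec$groups))) {
    grp <- spec$groups$group[i]
    n <- spec$groups$n[i]
    ci_n <- spec$groups$ci_n[i]
    vars <- spec$variables[spec$variables$group == grp, ]
    par <- function(v) {
      r <- vars[vars$variable == v, ]
      list(mean = r$mean, sd = sd_from_ci(r$mean, r$ci_low, r$ci_high, ci_n))
    }

    rec <- tibble::tibble(
      group = factor(grp, levels = group_levels),
      ethnicity = factor(
        rep(ethnicity_levels,
            times = c(spec$groups$malay[i], spec$groups$chinese[i],
                      spec$groups$indian[i])),
        levels = ethnicity_levels
      )
    )

    # correlated block first: one latent normal matrix, fixed column order
    z <- matrix(rnorm(n * length(copula_vars)), nrow = n)
    if (!is.null(latent_chol)) z <- z %*% latent_chol
    colnames(z) <- copula_vars
    for (v in copula_vars) {
      p <- par(v)
      if (v == "insulin") {
        # left-truncate at the 2 uU/mL assay detection limit via the inverse
        # CDF of the latent normal, preserving the copula rank structure
        sigma2 <- log(1 + (p$sd / p$mean)^2)
        mu <- log(p$mean) - sigma2 / 2
        p_floor <- stats::plnorm(2, mu, sqrt(sigma2))
        u <- p_floor + pnorm(z[, v]) * (1 - p_floor)
        rec[[v]] <- stats::qlnorm(u, mu, sqrt(sigma2))
      } else {
        rec[[v]] <- draw_lognormal(z[, v], p$mean, p$sd)
      }
    }

    # age: truncated normal on [40, 70], mean matched
    p <- par("age")
    mu <- trunc_normal_location(p$mean, p$sd, 40, 70)
    plo <- pnorm(40, mu, p$sd)
    phi <- pnorm(70, mu, p$sd)
    rec$age <- qnorm(plo + runif(n) * (phi - plo), mu, p$sd)

    for (v in c("sbp", "dbp")) {
      p <- par(v)
      rec[[v]] <- rnorm(n, p$mean, p$sd)
    }
    for (v in c("bmi", "waist", "whr", "total_chol", "hdl", "ldl",
                "tg", "hba1c")) {
      p <- par(v)
      rec[[v]] <- draw_lognormal(rnorm(n), p$mean, p$sd)
    }

    # enforce hdl < total_chol by redrawing the offending rows
    pc <- par("total_chol"); ph <- par("hdl")
    repeat {
      bad <- which(rec$hdl >= rec$total_chol)
      if (length(bad) == 0L) break
      rec$total_chol[bad] <- draw_lognormal(rnorm(length(bad)), pc$mean, pc$sd)
      rec$hdl[bad] <- draw_lognormal(rnorm(length(bad)), ph$mean, ph$sd)
    }

    for (v in c("smoking", "hypertension", "family_history")) {
      pr <- spec$binary$prob[spec$binary$variable == v & spec$binary$group == grp]
      rec[[v]] <- rbinom(n, 1L, pr) == 1L
    }
    out[[i]] <- rec
  }

  cohort <- dplyr::bind_rows(out)
  cohort <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(nrow(cohort)))),
    cohort
  )
  cohort <- cohort[, c("subject_id", "group", "ethnicity", "age", "bmi",
                       "waist", "whr", "sbp", "dbp", "total_chol", "hdl",
                       "ldl", "tg", "glucose", "hba1c", "insulin",
                       "adiponectin", "resistin", "smoking", "hypertension",
                       "family_history")]
  attr(cohort, "seed") <- seed
  attr(cohort, "scale") <- spec$scale
  cohort
}
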