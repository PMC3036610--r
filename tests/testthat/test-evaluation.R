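# Statistical harness: ANCOVA vs explicit least-squares oracle, BCa vs an
# independent reimplementation, MANCOVA vs matrix identities, Spearman vs
# brute force, and the orchestrated evaluation.

test_that("ANCOVA F vanishes when groups are identical", {
  withr::with_seed(1, {
    d <- tibble::tibble(
      y = rep(rnorm(15), 2),
      group = rep(c("a", "b"), each = 15),
      age = rep(rnorm(15, 50, 5), 2)
    )
    fit <- ancova_group_test(d, "y")
    expect_lt(fit$f_statistic, 1e-10)
  })
})

test_that("Type III ANCOVA F equals the full-vs-reduced least-squares oracle", {
  withr::with_seed(2, {
    for (i in 1:20) {
      d <- tibble::tibble(
        y = rnorm(30),
        group = sample(c("a", "b", "c"), 30, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)),
        age = rnorm(30, 50, 5)
      )
      while (any(table(d$group) < 3)) {
        d$group <- sample(c("a", "b", "c"), 30, replace = TRUE)
      }
      fit <- ancova_group_test(d, "y")
      expect_equal(fit$f_statistic, oracle_ancova_f(d$y, d$group, d$age),
                   tolerance = 1e-8)
    }
  })
})

test_that("rank-deficient designs and tiny groups are rejected", {
  d <- tibble::tibble(y = rnorm(20), group = rep(c("a", "b"), each = 10))
  d$age <- as.numeric(d$group == "a")  # covariate aliased with the factor
  expect_error(ancova_group_test(d, "y"), "aliased",
               class = "arindex_domain_error")
  d2 <- tibble::tibble(y = rnorm(5), group = c("a", "a", "a", "b", "b"),
                       age = rnorm(5))
  expect_error(ancova_group_test(d2, "y"), class = "arindex_domain_error")
})

test_that("BCa endpoints match an independent reimplementation to 1e-10", {
  withr::with_seed(3, {
    x <- rlnorm(10)
    strata <- rep(c("s1", "s2"), each = 5)
  })
  for (seed in c(11, 99, 2024)) {
    res <- bca_mean_interval(x, strata, replicates = 2000, seed = seed)
    oracle <- oracle_bca_mean(x, strata, B = 2000, level = 0.95, seed = seed)
    expect_equal(c(res$conf_low, res$conf_high), oracle, tolerance = 1e-10)
  }
  # and through the generic data-frame path with a mean statistic
  d <- data.frame(x = x, s = strata)
  res2 <- stratified_bca(d, function(d) mean(d$x), strata = "s",
                         replicates = 500, seed = 7)
  oracle2 <- oracle_bca_mean(x, strata, B = 500, level = 0.95, seed = 7)
  expect_equal(c(res2$conf_low, res2$conf_high), oracle2, tolerance = 1e-10)
})

test_that("with zero bias and acceleration BCa reduces to the percentile interval", {
  withr::with_seed(4, tstar <- rnorm(999))
  ends <- arindex:::bca_endpoints(tstar, z0 = 0, accel = 0, level = 0.95)
  ts <- sort(tstar)
  percentile <- vapply(c(0.025, 0.975), function(al) {
    k <- floor((length(ts) + 1) * al)
    ql <- qnorm(k / (length(ts) + 1)); qh <- qnorm((k + 1) / (length(ts) + 1))
    ts[k] + (qnorm(al) - ql) / (qh - ql) * (ts[k + 1] - ts[k])
  }, numeric(1))
  expect_equal(ends, percentile)
})

test_that("a degenerate bootstrap collapses to a point with a warning", {
  expect_warning(
    res <- bca_mean_interval(rep(2, 12), replicates = 200, seed = 5),
    "identical"
  )
  expect_equal(res$conf_low, 2)
  expect_equal(res$conf_high, 2)
})

test_that("BCa construction is equivariant under monotone transformation", {
  withr::with_seed(6, tstar <- rnorm(2000, 1, 0.2))
  z0 <- 0.13; a <- 0.04
  raw <- arindex:::bca_endpoints(tstar, z0, a, 0.95)
  transformed <- arindex:::bca_endpoints(exp(tstar), z0, a, 0.95)
  # interpolation happens on slightly different scales, so agreement is to
  # interpolation error, not exact
  expect_equal(transformed, exp(raw), tolerance = 1e-4)

  # end-to-end with a median statistic (commutes with exp), odd n
  withr::with_seed(61, x <- rnorm(21))
  r1 <- stratified_bca(data.frame(x = x), function(d) median(d$x),
                       replicates = 999, seed = 8)
  r2 <- stratified_bca(data.frame(x = exp(x)), function(d) median(d$x),
                       replicates = 999, seed = 8)
  expect_equal(c(r2$conf_low, r2$conf_high),
               exp(c(r1$conf_low, r1$conf_high)), tolerance = 0.02)
})

test_that("grades follow the nested-interval convention", {
  withr::with_seed(9, x <- rnorm(80, 3, 1))  # mean far from 0
  res <- bca_mean_interval(x, replicates = 1000, seed = 10)
  expect_equal(res$grade, "***")
  withr::with_seed(10, x0 <- rnorm(80, 0, 1))
  res0 <- bca_mean_interval(x0, replicates = 1000, seed = 10)
  expect_true(res0$grade %in% c("ns", "*"))
})

test_that("pairwise contrasts demand populated strata and report all pairs", {
  co <- small_cohort(seed = 12)
  pw <- pairwise_group_contrasts(co, "glucose", replicates = 200, seed = 13)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$grade %in% c("ns", "*", "**", "***")))
  # the glucose gap between controls and T2DM groups is designed-in
  big <- pw[pw$group_i == "control" & pw$group_j == "t2dm_ms", ]
  expect_equal(big$grade, "***")
  broken <- co[!(co$group == "control" & co$ethnicity == "indian"), ]
  expect_error(pairwise_group_contrasts(broken, "glucose", replicates = 100),
               "stratum", class = "arindex_domain_error")
})

test_that("multivariate statistics follow their eigenvalue identities", {
  lam <- 0.7
  tab <- mv_stats_from_eigen(lam)
  v <- setNames(tab$value, tab$statistic)
  expect_equal(unname(v["pillai"]), lam / (1 + lam))
  expect_equal(unname(v["wilks"]), 1 / (1 + lam))
  expect_equal(unname(v["hotelling"]), lam)
  expect_equal(unname(v["roy"]), lam)
  expect_error(mv_stats_from_eigen(c(0.2, -0.1)), class = "arindex_domain_error")
})

test_that("MANCOVA matches the matrix-identity oracle on simulated data", {
  withr::with_seed(14, {
    for (i in 1:10) {
      n <- 60
      g <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
      while (any(table(g) < 3)) g <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
      age <- rnorm(n, 50, 5)
      Y <- cbind(rnorm(n, 8 + (g == "d"), 2), rnorm(n, 12 - (g == "a"), 3))
      d <- tibble::tibble(adiponectin = Y[, 1], resistin = Y[, 2],
                          age = age, group = g)
      fit <- mancova_group_test(d)
      oracle <- oracle_mancova_stats(Y, g, age)
      got <- setNames(fit$table$value, fit$table$statistic)
      expect_equal(unname(got[names(oracle)]), unname(oracle), tolerance = 1e-8)
    }
  })
})

test_that("MANCOVA at the full study size reproduces the published df layout", {
  co <- generate_cohort(default_cohort_spec(), seed = 15)
  fit <- mancova_group_test(co)
  expect_equal(fit$table$df1, c(6, 6, 6, 3))
  expect_equal(fit$table$df2, c(1608, 1606, 1604, 804))
  expect_equal(fit$df_hypothesis, 3)
  expect_equal(fit$df_error, 804)
})

test_that("Spearman matrix matches brute force, handles ties, and is rank-invariant", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3), z = c(3, 2, 1))
  sp <- spearman_matrix(d, c("x", "y", "z"))
  expect_equal(sp$rho["x", "y"], 1)
  expect_equal(sp$rho["x", "z"], -1)
  expect_equal(sp$p_value["x", "y"], 0)

  withr::with_seed(16, {
    x <- sample(1:6, 20, replace = TRUE)  # heavy ties
    y <- x + sample(1:4, 20, replace = TRUE)
    d2 <- tibble::tibble(x = x, y = y)
    sp2 <- spearman_matrix(d2, c("x", "y"))
    expect_equal(sp2$rho["x", "y"], oracle_spearman(x, y), tolerance = 1e-12)
    # t-approximation p-value recomputed directly
    r <- sp2$rho["x", "y"]
    tval <- r * sqrt((20 - 2) / (1 - r^2))
    expect_equal(sp2$p_value["x", "y"], 2 * pt(-abs(tval), 18), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    sp3 <- spearman_matrix(tibble::tibble(x = exp(x), y = y^3), c("x", "y"))
    expect_equal(sp3$rho["x", "y"], sp2$rho["x", "y"], tolerance = 1e-12)
  })
  expect_warning(spearman_matrix(tibble::tibble(x = rep(1, 10), y = 1:10),
                                 c("x", "y")), "Constant")
})

test_that("the orchestrated evaluation is structurally complete and consistent", {
  co <- generate_cohort(default_cohort_spec(scale = 0.25), seed = 17)
  ev <- evaluate_case_control(co, replicates = 200, seed = 18)
  expect_s3_class(ev, "ar_evaluation")
  expect_equal(nrow(ev$comparisons), 21)
  expect_true(all(vapply(ev$comparisons$pairwise, nrow, integer(1)) == 6))
  # reported raw group means equal direct group averages
  direct <- tapply(ev$indexed$insulin, ev$indexed$group, mean)
  got <- ev$group_summary[ev$group_summary$variable == "insulin", ]
  expect_equal(got$mean[match(names(direct), got$group)],
               as.numeric(direct), tolerance = 1e-12)
  expect_equal(sort(unique(ev$correlations_clinical$against)),
               sort(c("adiponectin", "resistin", "ar")))
  # determinism given the seed
  ev2 <- evaluate_case_control(co, replicates = 200, seed = 18)
  expect_identical(tidy(ev), tidy(ev2))
  expect_identical(ev$comparisons$pairwise, ev2$comparisons$pairwise)
  expect_error(evaluate_case_control(co, replicates = 50),
               class = "arindex_domain_error")
  expect_error(evaluate_case_control(co[co$group != "control", ],
                                     replicates = 200),
               class = "arindex_domain_error")
})
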