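# Synthetic cohort: design counts, determinism, record invariants and
# calibration against the generator's own targets.

test_that("sd_from_ci back-derives the standard deviation", {
  expect_equal(sd_from_ci(10.99, 10.05, 11.97, 208), 7.0641, tolerance = 1e-4)
  expect_equal(sd_from_ci(0, -1.959964, 1.959964, 4), 2)
  expect_error(sd_from_ci(5, 5, 5, 100), class = "arindex_domain_error")
  expect_error(sd_from_ci(5, 4, 6, 1), class = "arindex_domain_error")
})

test_that("the default specification carries the study design", {
  spec <- default_cohort_spec()
  expect_equal(sum(spec$groups$n), 809L)
  expect_equal(spec$groups$n, c(208L, 174L, 171L, 256L))
  expect_equal(spec$groups$malay, c(75L, 62L, 43L, 101L))
  expect_equal(spec$groups$chinese, c(73L, 54L, 62L, 75L))
  expect_equal(spec$groups$indian, c(60L, 58L, 66L, 80L))
  glu <- spec$variables[spec$variables$variable == "glucose" &
                          spec$variables$group == "control", ]
  expect_equal(glu$mean, 5.13)
  expect_equal(c(glu$ci_low, glu$ci_high), c(5.05, 5.23))
  expect_true(all(spec$variables$ci_low < spec$variables$mean &
                    spec$variables$mean < spec$variables$ci_high))
})

test_that("scaling rounds half up and keeps ethnicity sums exact", {
  spec <- default_cohort_spec(scale = 0.1)
  expect_equal(spec$groups$n, c(21L, 17L, 17L, 26L))
  expect_equal(spec$groups$malay + spec$groups$chinese + spec$groups$indian,
               spec$groups$n)
})

test_that("generation is deterministic and honours the exact design counts", {
  spec <- default_cohort_spec(scale = 0.1)
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(dplyr::as_tibble(a), dplyr::as_tibble(b))
  c2 <- generate_cohort(spec, seed = 43)
  expect_false(identical(a$insulin, c2$insulin))
  counts <- table(a$group, a$ethnicity)
  expect_equal(as.integer(t(counts)),
               as.integer(t(as.matrix(spec$groups[, c("malay", "chinese", "indian")]))))
})

test_that("every generated record satisfies the schema invariants", {
  co <- generate_cohort(default_cohort_spec(scale = 0.5), seed = 9)
  num_cols <- c("bmi", "waist", "whr", "sbp", "dbp", "total_chol", "hdl",
                "ldl", "tg", "glucose", "hba1c", "insulin", "adiponectin",
                "resistin")
  expect_true(all(vapply(co[num_cols], function(x) all(x > 0), logical(1))))
  expect_true(all(co$age >= 40 & co$age <= 70))
  expect_true(all(co$hdl < co$total_chol))
  expect_false(anyNA(co))
})

test_that("group mean insulin stays within 3 SE of its target across seeds", {
  spec <- default_cohort_spec()
  targets <- spec$variables[spec$variables$variable == "insulin", ]
  hits <- vapply(1:200, function(s) {
    co <- generate_cohort(spec, seed = 1000 + s)
    ok <- TRUE
    for (i in seq_len(nrow(spec$groups))) {
      g <- spec$groups$group[i]
      row <- targets[targets$group == g, ]
      sd_g <- sd_from_ci(row$mean, row$ci_low, row$ci_high, spec$groups$ci_n[i])
      se <- sd_g / sqrt(spec$groups$n[i])
      ok <- ok && abs(mean(co$insulin[co$group == g]) - row$mean) <= 3 * se
    }
    ok
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("infeasible correlation targets are rejected before sampling", {
  bad <- diag(4)
  dimnames(bad) <- list(arindex:::copula_vars, arindex:::copula_vars)
  bad[1, 2] <- bad[2, 1] <- 0.95
  bad[1, 3] <- bad[3, 1] <- 0.95
  bad[2, 3] <- bad[3, 2] <- -0.95
  expect_error(default_cohort_spec(spearman_targets = bad),
               class = "arindex_domain_error")
})

test_that("the copula induces the targeted negative adipokine correlation within groups", {
  co <- generate_cohort(default_cohort_spec(scale = 10), seed = 21)
  ctrl <- co[co$group == "control", ]
  rho <- cor(ctrl$adiponectin, ctrl$resistin, method = "spearman")
  expect_lt(rho, -0.05)
  expect_gt(rho, -0.17)
})
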