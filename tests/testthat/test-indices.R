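# Index formulas: analytic cases, unit handling, and agreement with
# independent oracles.

test_that("glucose conversion applies the dialect factor and rejects bad input", {
  expect_equal(glucose_to_mgdl(1), 18.0182)
  expect_equal(glucose_to_mgdl(5.13), 92.433366, tolerance = 1e-9)
  expect_equal(glucose_to_mgdl(1, formula_dialect(glucose_factor = 18)), 18)
  expect_error(glucose_to_mgdl(0), class = "arindex_domain_error")
  expect_error(glucose_to_mgdl(-1), class = "arindex_domain_error")
})

test_that("AR index matches its analytic values and rejects non-positive inputs", {
  expect_equal(ar_index(10, 10), 1)
  expect_equal(ar_index(10, 20), 1 + log10(2))
  expect_equal(ar_index(20, 10), 1 - log10(2))
  expect_error(ar_index(0, 10), class = "arindex_domain_error")
  expect_error(ar_index(10, c(5, -1)), class = "arindex_domain_error")
})

test_that("QUICKI handles units and its domain boundary", {
  # force a pure-number check through an identity dialect and mg/dL inputs
  raw <- formula_dialect(glucose_factor = 1)
  expect_equal(quicki(10, 10, raw), 0.5)
  expect_equal(quicki(1, 10, raw), 1)
  expect_equal(quicki(10.99, 5.13), 0.332576559721, tolerance = 1e-10)
  expect_error(quicki(1, 1, raw), class = "arindex_domain_error")
  expect_error(quicki(0.5, 1.5, raw), class = "arindex_domain_error")
})

test_that("HOMA-IR is the scaled insulin-glucose product", {
  expect_equal(homa_ir(22.5, 1), 1)
  expect_equal(homa_ir(22.5, 2), 2)
  expect_equal(homa_ir(10.99, 5.13), 2.50572, tolerance = 1e-10)
  expect_error(homa_ir(-1, 5), class = "arindex_domain_error")
})

test_that("Bennett index respects the dialect and its log-domain precondition", {
  expect_equal(bennett_index(exp(1), exp(1)), 1)
  expect_equal(bennett_index(10.99, 5.13), 0.255145975722, tolerance = 1e-10)
  expect_equal(bennett_index(10, 10, formula_dialect(bennett_log_base = "base10")), 1)
  expect_error(bennett_index(1, 5.13), class = "arindex_domain_error")
  expect_error(bennett_index(0.9, 5.13), class = "arindex_domain_error")
})

test_that("McAuley indexes match their closed forms and decrease in insulin", {
  expect_equal(mcauley_tg_index(1, 1), exp(2.63))
  expect_equal(mcauley_ins_index(1), exp(2.63))
  expect_equal(mcauley_tg_index(10.99, 1.31), 6.52170322275, tolerance = 1e-10)
  expect_equal(mcauley_ins_index(10.99), 7.09112487731, tolerance = 1e-10)
  withr::with_seed(11, {
    i0 <- exp(runif(50, log(2), log(40)))
    expect_true(all(mcauley_ins_index(2 * i0) < mcauley_ins_index(i0)))
    expect_true(all(mcauley_tg_index(2 * i0, 1.5) < mcauley_tg_index(i0, 1.5)))
  })
})

test_that("IR_AR expanded form matches the derived example and collapses when R0 = A0", {
  expect_equal(irar_index(10.99, 5.13, 10, 20), 3.91197141721, tolerance = 1e-10)
  # equal numeric adipokine values: the correction term vanishes
  expect_equal(irar_index(10.99, 5.13, 7, 7), 3.00682646076, tolerance = 1e-10)
})

test_that("IR_AR equals AR/QUICKI and the oracles agree to 12 significant digits", {
  withr::with_seed(42, {
    d <- random_index_inputs(1000)
    irar <- irar_index(d$insulin, d$glucose, d$adiponectin, d$resistin)
    ratio <- ar_index(d$adiponectin, d$resistin) /
      quicki(d$insulin, d$glucose)
    expect_lt(max(abs(irar - ratio) / abs(ratio)), 1e-12)
    expect_lt(max(abs(ar_index(d$adiponectin, d$resistin) -
                        oracle_ar(d$adiponectin, d$resistin))), 1e-12)
    expect_lt(max(abs(quicki(d$insulin, d$glucose) -
                        oracle_quicki(d$insulin, d$glucose)) /
                    oracle_quicki(d$insulin, d$glucose)), 1e-12)
    expect_lt(max(abs(homa_ir(d$insulin, d$glucose) -
                        oracle_homa(d$insulin, d$glucose)) /
                    oracle_homa(d$insulin, d$glucose)), 1e-12)
    expect_lt(max(abs(mcauley_tg_index(d$insulin, d$tg) -
                        oracle_mcauley_tg(d$insulin, d$tg)) /
                    oracle_mcauley_tg(d$insulin, d$tg)), 1e-12)
    expect_lt(max(abs(irar - oracle_irar(d$insulin, d$glucose,
                                         d$adiponectin, d$resistin)) /
                    abs(irar)), 1e-12)
  })
})

test_that("AR index is monotone in each adipokine and invariant to common scaling", {
  withr::with_seed(7, {
    a0 <- exp(runif(200, log(1), log(30)))
    r0 <- exp(runif(200, log(2), log(60)))
    eps <- 1e-6
    expect_true(all(ar_index(a0, r0 + eps) > ar_index(a0, r0)))
    expect_true(all(ar_index(a0 + eps, r0) < ar_index(a0, r0)))
    k <- runif(200, 0.1, 10)
    expect_equal(ar_index(k * a0, k * r0), ar_index(a0, r0), tolerance = 1e-12)
  })
})

test_that("QUICKI and HOMA-IR move in opposite directions", {
  withr::with_seed(8, {
    d <- random_index_inputs(200)
    up <- 1.1
    expect_true(all(homa_ir(up * d$insulin, d$glucose) > homa_ir(d$insulin, d$glucose)))
    expect_true(all(quicki(up * d$insulin, d$glucose) < quicki(d$insulin, d$glucose)))
    expect_true(all(homa_ir(d$insulin, up * d$glucose) > homa_ir(d$insulin, d$glucose)))
    expect_true(all(quicki(d$insulin, up * d$glucose) < quicki(d$insulin, d$glucose)))
  })
})

test_that("compute_indices appends a consistent panel and handles missing TG", {
  inputs <- tibble::tibble(insulin = 10.99, glucose = 5.13,
                           adiponectin = 10, resistin = 10, tg = 1.31)
  panel <- compute_indices(inputs)
  expect_equal(panel$ar, 1)
  expect_equal(panel$homa_ir, 2.50572, tolerance = 1e-9)
  expect_equal(panel$quicki, 0.332576559721, tolerance = 1e-9)
  expect_equal(panel$ir_ar, 3.00682646076, tolerance = 1e-9)
  expect_equal(panel$ir_ar, panel$ar / panel$quicki, tolerance = 1e-12)

  expect_warning(out <- compute_indices(dplyr::select(inputs, -tg)),
                 "mcauley_tg")
  expect_true(is.na(out$mcauley_tg))
  expect_error(compute_indices(dplyr::select(inputs, -tg), require_all = TRUE),
               "mcauley_tg", class = "arindex_domain_error")
  expect_error(index_panel(10.99, 5.13, 10, 10), "tg",
               class = "arindex_domain_error")
  expect_error(compute_indices(dplyr::select(inputs, -insulin)),
               class = "arindex_schema_error")
})
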