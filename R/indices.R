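#' Adiponectin-resistin (AR) index
#'
#' The AR index unifies the two adipokines as
#' \eqn{AR = 1 + \log_{10}(R_0) - \log_{10}(A_0)}, with resistin \eqn{R_0} in
#' ng/mL and adiponectin \eqn{A_0} in ug/mL. The unit asymmetry of the ratio is
#' part of the definition and is deliberately preserved: the numeric values in
#' those units enter the logs directly. Higher values indicate worse metabolic
#' status.
#'
#' @param adiponectin fasting serum total adiponectin, ug/mL.
#' @param resistin fasting serum total resistin, ng/mL.
#' @return dimensionless AR index, vectorised over the inputs.
#' @examples
#' ar_index(adiponectin = 10, resistin = 20) # 1 + log10(2)
#' @export
ar_index <- function(adiponectin, resistin) {
  check_positive(adiponectin, "adiponectin")
  check_positive(resistin, "resistin")
  1 + log10(resistin) - log10(adiponectin)
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' \eqn{QUICKI = 1 / [\log_{10}(I_0) + \log_{10}(G_0)]} with fasting insulin
#' \eqn{I_0} in uU/mL and fasting glucose \eqn{G_0} in mg/dL. Glucose is
#' supplied in mmol/L (the reporting unit) and converted through the dialect.
#'
#' @param insulin fasting serum insulin, uU/mL.
#' @param glucose fasting plasma glucose, mmol/L.
#' @param dialect a [formula_dialect()].
#' @return dimensionless QUICKI, vectorised.
#' @examples
#' quicki(insulin = 10.99, glucose = 5.13)
#' @export
quicki <- function(insulin, glucose, dialect = formula_dialect()) {
  check_positive(insulin, "insulin")
  g_mgdl <- glucose_to_mgdl(glucose, dialect)
  denom <- log10(insulin) + log10(g_mgdl)
  if (any(denom <= 0)) {
    abort(
      "QUICKI undefined/non-positive: insulin x glucose (mg/dL) must exceed 1.",
      class = "arindex_domain_error"
    )
  }
  1 / denom
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' \eqn{HOMA\mbox{-}IR = I_0 \times G_0(mmol/L) / 22.5}.
#'
#' @inheritParams quicki
#' @return dimensionless HOMA-IR, vectorised.
#' @examples
#' homa_ir(insulin = 10.99, glucose = 5.13)
#' @export
homa_ir <- function(insulin, glucose) {
  check_positive(insulin, "insulin")
  check_positive(glucose, "glucose")
  insulin * glucose / 22.5
}

#' Bennett insulin sensitivity index
#'
#' \eqn{1 / [\log(I_0) \times \log(G_0)]}. The log base and glucose unit are
#' dialect choices; the default (natural log, glucose in mmol/L) is the only
#' combination whose value at typical control means sits below the reciprocal's
#' group mean, as Jensen's inequality for the convex reciprocal requires.
#'
#' @inheritParams quicki
#' @return dimensionless Bennett index, vectorised.
#' @examples
#' bennett_index(insulin = exp(1), glucose = exp(1)) # 1
#' @export
bennett_index <- function(insulin, glucose, dialect = formula_dialect()) {
  check_positive(insulin, "insulin")
  check_positive(glucose, "glucose")
  g <- if (dialect$bennett_glucose_unit == "mg/dL") {
    glucose * dialect$glucose_factor
  } else {
    glucose
  }
  lg <- if (dialect$bennett_log_base == "natural") log else log10
  li <- lg(insulin)
  lgg <- lg(g)
  if (any(li <= 0) || any(lgg <= 0)) {
    abort(
      "Bennett index undefined: log(insulin) and log(glucose) must both be positive.",
      class = "arindex_domain_error"
    )
  }
  1 / (li * lgg)
}

#' McAuley insulin sensitivity indexes
#'
#' `mcauley_tg_index()` is the published insulin + triglyceride regression
#' \eqn{\exp(c_0 - c_1 \ln I_0 - c_2 \ln TG)}; `mcauley_ins_index()` drops the
#' triglyceride term. Coefficients live in the dialect
#' (defaults 2.63, 0.28, 0.31).
#'
#' @inheritParams quicki
#' @param tg fasting serum triglyceride, mmol/L.
#' @return dimensionless index, vectorised.
#' @examples
#' mcauley_tg_index(insulin = 10.99, tg = 1.31)
#' mcauley_ins_index(insulin = 10.99)
#' @export
mcauley_tg_index <- function(insulin, tg, dialect = formula_dialect()) {
  check_positive(insulin, "insulin")
  check_positive(tg, "tg")
  co <- dialect$mcauley_tg_coef
  exp(co[1] - co[2] * log(insulin) - co[3] * log(tg))
}

#' @rdname mcauley_tg_index
#' @export
mcauley_ins_index <- function(insulin, dialect = formula_dialect()) {
  check_positive(insulin, "insulin")
  co <- dialect$mcauley_ins_coef
  exp(co[1] - co[2] * log(insulin))
}

#' IR_AR insulin-resistance index
#'
#' The AR index folded into QUICKI:
#' \eqn{IR_{AR} = AR / QUICKI = \log_{10}(I_0 G_0)\,[1 + \log_{10}(R_0/A_0)]}
#' with glucose \eqn{G_0} in mg/dL. The expanded form is evaluated directly and
#' agrees with `ar_index()/quicki()` to machine precision (an identity the test
#' suite enforces at 1e-12 relative tolerance).
#'
#' @inheritParams quicki
#' @inheritParams ar_index
#' @return dimensionless IR_AR index, vectorised.
#' @examples
#' irar_index(insulin = 10.99, glucose = 5.13, adiponectin = 10, resistin = 20)
#' @export
irar_index <- function(insulin, glucose, adiponectin, resistin,
                       dialect = formula_dialect()) {
  check_positive(adiponectin, "adiponectin")
  check_positive(resistin, "resistin")
  check_positive(insulin, "insulin")
  g_mgdl <- glucose_to_mgdl(glucose, dialect)
  denom <- log10(insulin) + log10(g_mgdl)
  if (any(denom <= 0)) {
    abort(
      "IR_AR undefined: insulin x glucose (mg/dL) must exceed 1 (QUICKI precondition).",
      class = "arindex_domain_error"
    )
  }
  denom * (1 + log10(resistin / adiponectin))
}

#' Compute the full seven-index panel for a cohort
#'
#' Data-frame-first wrapper: takes one row per subject with columns `insulin`
#' (uU/mL), `glucose` (mmol/L), `adiponectin` (ug/mL), `resistin` (ng/mL) and
#' optionally `tg` (mmol/L), and appends the seven index columns `ar`,
#' `quicki`, `homa_ir`, `bennett`, `mcauley_tg`, `mcauley_ins`, `ir_ar`.
#'
#' If `tg` is absent the McAuley triglyceride index is emitted as `NA` with a
#' warning unless `require_all = TRUE`, in which case the missing input is an
#' error naming the index it starves.
#'
#' @param data data frame of subject records.
#' @param dialect a [formula_dialect()].
#' @param require_all error (rather than warn) when an optional input needed by
#'   one index is missing.
#' @return `data` as a tibble with the seven index columns appended.
#' @examples
#' tibble::tibble(
#'   insulin = 10.99, glucose = 5.13,
#'   adiponectin = 10, resistin = 10, tg = 1.31
#' ) |>
#'   compute_indices()
#' @export
compute_indices <- function(data, dialect = formula_dialect(),
                            require_all = FALSE) {
  for (col in c("insulin", "glucose", "adiponectin", "resistin")) {
    check_column(data, col, "compute_indices")
  }
  out <- tibble::as_tibble(data)
  out$ar <- ar_index(out$adiponectin, out$resistin)
  out$quicki <- quicki(out$insulin, out$glucose, dialect)
  out$homa_ir <- homa_ir(out$insulin, out$glucose)
  out$bennett <- bennett_index(out$insulin, out$glucose, dialect)
  if ("tg" %in% names(out)) {
    out$mcauley_tg <- mcauley_tg_index(out$insulin, out$tg, dialect)
  } else if (require_all) {
    abort("`tg` is required to compute the mcauley_tg index.",
          class = "arindex_domain_error")
  } else {
    warn("`tg` column missing: mcauley_tg emitted as NA.")
    out$mcauley_tg <- NA_real_
  }
  out$mcauley_ins <- mcauley_ins_index(out$insulin, dialect)
  out$ir_ar <- irar_index(out$insulin, out$glucose, out$adiponectin,
                          out$resistin, dialect)
  out
}

#' Seven-index panel for a single subject
#'
#' Scalar convenience around [compute_indices()] that requires every input
#' (including triglyceride) and returns a one-row tibble.
#'
#' @inheritParams quicki
#' @inheritParams ar_index
#' @param tg fasting serum triglyceride, mmol/L.
#' @return one-row tibble with columns `ar`, `quicki`, `homa_ir`, `bennett`,
#'   `mcauley_tg`, `mcauley_ins`, `ir_ar`.
#' @examples
#' index_panel(insulin = 10.99, glucose = 5.13, adiponectin = 10,
#'             resistin = 10, tg = 1.31)
#' @export
index_panel <- function(insulin, glucose, adiponectin, resistin, tg,
                        dialect = formula_dialect()) {
  if (missing(tg)) {
    abort("`tg` is required to compute the mcauley_tg index.",
          class = "arindex_domain_error")
  }
  inputs <- tibble::tibble(
    insulin = insulin, glucose = glucose,
    adiponectin = adiponectin, resistin = resistin, tg = tg
  )
  compute_indices(inputs, dialect, require_all = TRUE)[
    , c("ar", "quicki", "homa_ir", "bennett",
        "mcauley_tg", "mcauley_ins", "ir_ar")
  ]
}
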