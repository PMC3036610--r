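#' Formula dialect for the surrogate insulin-sensitivity indexes
#'
#' Several of the classical surrogate indexes circulate in the literature in
#' more than one algebraic dress (log base, glucose unit, regression
#' coefficients). A `formula_dialect` pins every such choice down so a whole
#' analysis is reproducible from its configuration alone.
#'
#' @param glucose_factor mg/dL per mmol/L conversion factor for fasting plasma
#'   glucose. Default 18.0182 (the molar mass of glucose, g/mol, divided by 10).
#' @param bennett_log_base `"natural"` (default) or `"base10"`: logarithm used
#'   inside the Bennett index.
#' @param bennett_glucose_unit `"mmol/L"` (default) or `"mg/dL"`: glucose unit
#'   fed to the Bennett index.
#' @param mcauley_ins_coef numeric length 2, `(intercept, insulin coefficient)`
#'   of the insulin-only McAuley regression; default `c(2.63, 0.28)`.
#' @param mcauley_tg_coef numeric length 3,
#'   `(intercept, insulin coefficient, triglyceride coefficient)` of the
#'   insulin + triglyceride McAuley regression; default `c(2.63, 0.28, 0.31)`.
#'
#' @return An object of class `formula_dialect`.
#' @examples
#' formula_dialect()
#' formula_dialect(glucose_factor = 18)
#' @export
formula_dialect <- function(glucose_factor = 18.0182,
                            bennett_log_base = c("natural", "base10"),
                            bennett_glucose_unit = c("mmol/L", "mg/dL"),
                            mcauley_ins_coef = c(2.63, 0.28),
                            mcauley_tg_coef = c(2.63, 0.28, 0.31)) {
  bennett_log_base <- match.arg(bennett_log_base)
  bennett_glucose_unit <- match.arg(bennett_glucose_unit)
  if (!is.numeric(glucose_factor) || length(glucose_factor) != 1L ||
      !is.finite(glucose_factor) || glucose_factor <= 0) {
    abort("`glucose_factor` must be a single positive number.",
          class = "arindex_domain_error")
  }
  if (length(mcauley_ins_coef) != 2L || length(mcauley_tg_coef) != 3L) {
    abort("McAuley coefficient vectors must have lengths 2 and 3.",
          class = "arindex_domain_error")
  }
  structure(
    list(
      glucose_factor = glucose_factor,
      bennett_log_base = bennett_log_base,
      bennett_glucose_unit = bennett_glucose_unit,
      mcauley_ins_coef = as.numeric(mcauley_ins_coef),
      mcauley_tg_coef = as.numeric(mcauley_tg_coef)
    ),
    class = "formula_dialect"
  )
}

#' @export
print.formula_dialect <- function(x, ...) {
  cat("<formula_dialect>\n")
  cat("  glucose mmol/L -> mg/dL factor:", x$glucose_factor, "\n")
  cat("  Bennett: log =", x$bennett_log_base, ", glucose in", x$bennett_glucose_unit, "\n")
  cat("  McAuley (insulin):      exp(", x$mcauley_ins_coef[1], "-",
      x$mcauley_ins_coef[2], "ln I0 )\n")
  cat("  McAuley (insulin, TG):  exp(", x$mcauley_tg_coef[1], "-",
      x$mcauley_tg_coef[2], "ln I0 -", x$mcauley_tg_coef[3], "ln TG )\n")
  invisible(x)
}

#' Convert fasting plasma glucose from mmol/L to mg/dL
#'
#' @param glucose_mmol fasting plasma glucose, mmol/L (strictly positive).
#' @param dialect a [formula_dialect()] supplying the conversion factor.
#' @return glucose in mg/dL.
#' @examples
#' glucose_to_mgdl(5.13)
#' @export
glucose_to_mgdl <- function(glucose_mmol, dialect = formula_dialect()) {
  check_positive(glucose_mmol, "glucose_mmol")
  glucose_mmol * dialect$glucose_factor
}
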