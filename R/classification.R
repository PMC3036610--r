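#' Published risk-band thresholds for the AR and IR_AR indexes
#'
#' The defaults are the cut-offs published for Malaysian men aged 40-70: they
#' were derived from the 95% confidence intervals of the group means, not from
#' ROC analysis, and recalibration for other populations is a configuration
#' change, not a code change.
#'
#' AR index ladder: healthy reference range `[1.120, 1.206]`; minimum cut-off
#' zone `(1.206, 1.244)`; `>= 1.244` metabolic syndrome / pre-diabetic;
#' `>= 1.379` type 2 diabetes; `>= 1.559` T2DM with MS.
#'
#' IR_AR ladder: insulin-sensitive reference `[3.265, 3.538]`; minimum cut-off
#' zone `(3.538, 3.955)`; mild `[3.955, 4.305]`, moderate `[4.403, 4.791]`,
#' severe `[5.305, 5.612]` published bands. The published bands leave gaps
#' (4.305-4.403 and 4.791-5.305); classification is made total by extending
#' each band to the next band's lower bound, so only the explicitly published
#' minimum cut-off zones remain indeterminate.
#'
#' @param ar_healthy_range closed interval of the healthy AR reference range.
#' @param ar_cutoffs named vector `c(ms=, t2dm=, t2dm_ms=)` of AR cut-offs;
#'   boundary values classify into the higher-severity band ("or greater").
#' @param irar_sensitive_range closed interval, insulin-sensitive IR_AR range.
#' @param irar_mild_band,irar_moderate_band,irar_severe_band published IR_AR
#'   bands (closed intervals).
#' @return object of class `risk_thresholds`.
#' @examples
#' risk_thresholds()
#' @export
risk_thresholds <- function(ar_healthy_range = c(1.120, 1.206),
                            ar_cutoffs = c(ms = 1.244, t2dm = 1.379,
                                           t2dm_ms = 1.559),
                            irar_sensitive_range = c(3.265, 3.538),
                            irar_mild_band = c(3.955, 4.305),
                            irar_moderate_band = c(4.403, 4.791),
                            irar_severe_band = c(5.305, 5.612)) {
  ar_ladder <- c(ar_healthy_range, ar_cutoffs)
  irar_ladder <- c(irar_sensitive_range, irar_mild_band,
                   irar_moderate_band, irar_severe_band)
  if (any(diff(ar_ladder) <= 0) || any(diff(irar_ladder) <= 0)) {
    abort("Threshold ladders must be strictly increasing.",
          class = "arindex_domain_error")
  }
  structure(
    list(
      ar_healthy_range = as.numeric(ar_healthy_range),
      ar_cutoffs = c(ms = unname(ar_cutoffs[1]),
                     t2dm = unname(ar_cutoffs[2]),
                     t2dm_ms = unname(ar_cutoffs[3])),
      irar_sensitive_range = as.numeric(irar_sensitive_range),
      irar_mild_band = as.numeric(irar_mild_band),
      irar_moderate_band = as.numeric(irar_moderate_band),
      irar_severe_band = as.numeric(irar_severe_band)
    ),
    class = "risk_thresholds"
  )
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat("<risk_thresholds>\n")
  cat(sprintf("  AR   healthy [%.3f, %.3f]; cut-offs MS %.3f | T2DM %.3f | T2DM+MS %.3f\n",
              x$ar_healthy_range[1], x$ar_healthy_range[2],
              x$ar_cutoffs["ms"], x$ar_cutoffs["t2dm"], x$ar_cutoffs["t2dm_ms"]))
  cat(sprintf("  IR_AR sensitive [%.3f, %.3f]; mild [%.3f, %.3f]; moderate [%.3f, %.3f]; severe [%.3f, %.3f]\n",
              x$irar_sensitive_range[1], x$irar_sensitive_range[2],
              x$irar_mild_band[1], x$irar_mild_band[2],
              x$irar_moderate_band[1], x$irar_moderate_band[2],
              x$irar_severe_band[1], x$irar_severe_band[2]))
  invisible(x)
}

ar_band_levels <- c("healthy", "indeterminate", "ms_prediabetic",
                    "t2dm", "t2dm_with_ms")
irar_band_levels <- c("insulin_sensitive", "indeterminate", "mild_ir",
                      "moderate_ir", "severe_ir")

#' Classify AR index values into risk bands
#'
#' Total, deterministic partition of the real line: values at or below the
#' upper healthy bound are `healthy` (the published range bounds group means,
#' not individual floors, so very low values are healthy too); the published
#' minimum cut-off zone is `indeterminate`; each cut-off is left-closed
#' ("or greater" classifies into the higher-severity band).
#'
#' @param ar_value finite numeric vector of AR index values.
#' @param thresholds a [risk_thresholds()].
#' @return ordered factor with levels healthy < indeterminate <
#'   ms_prediabetic < t2dm < t2dm_with_ms.
#' @examples
#' classify_ar(c(1.15, 1.22, 1.30, 1.45, 1.60))
#' @export
classify_ar <- function(ar_value, thresholds = risk_thresholds()) {
  if (!is.numeric(ar_value) || any(!is.finite(ar_value))) {
    abort("`ar_value` must be finite numeric.", class = "arindex_domain_error")
  }
  cut_ms <- thresholds$ar_cutoffs["ms"]
  cut_t2dm <- thresholds$ar_cutoffs["t2dm"]
  cut_both <- thresholds$ar_cutoffs["t2dm_ms"]
  healthy_hi <- thresholds$ar_healthy_range[2]
  band <- dplyr::case_when(
    ar_value >= cut_both ~ "t2dm_with_ms",
    ar_value >= cut_t2dm ~ "t2dm",
    ar_value >= cut_ms ~ "ms_prediabetic",
    ar_value > healthy_hi ~ "indeterminate",
    TRUE ~ "healthy"
  )
  factor(band, levels = ar_band_levels, ordered = TRUE)
}

#' Classify IR_AR index values into insulin-resistance bands
#'
#' @param irar_value finite numeric vector of IR_AR index values.
#' @inheritParams classify_ar
#' @return ordered factor with levels insulin_sensitive < indeterminate <
#'   mild_ir < moderate_ir < severe_ir.
#' @examples
#' classify_irar(c(3.40, 3.70, 4.10, 4.60, 5.50))
#' @export
classify_irar <- function(irar_value, thresholds = risk_thresholds()) {
  if (!is.numeric(irar_value) || any(!is.finite(irar_value))) {
    abort("`irar_value` must be finite numeric.", class = "arindex_domain_error")
  }
  sens_hi <- thresholds$irar_sensitive_range[2]
  mild_lo <- thresholds$irar_mild_band[1]
  mod_lo <- thresholds$irar_moderate_band[1]
  sev_lo <- thresholds$irar_severe_band[1]
  band <- dplyr::case_when(
    irar_value >= sev_lo ~ "severe_ir",
    irar_value >= mod_lo ~ "moderate_ir",
    irar_value >= mild_lo ~ "mild_ir",
    irar_value > sens_hi ~ "indeterminate",
    TRUE ~ "insulin_sensitive"
  )
  factor(band, levels = irar_band_levels, ordered = TRUE)
}

#' Append risk-band columns to an indexed cohort
#'
#' Data-frame-first composition of [classify_ar()] and [classify_irar()]:
#' expects `ar` and `ir_ar` columns (as produced by [compute_indices()]) and
#' appends `ar_band` and `irar_band`.
#'
#' @param data data frame with `ar` and `ir_ar` columns.
#' @inheritParams classify_ar
#' @return `data` as a tibble with `ar_band` and `irar_band` appended.
#' @examples
#' tibble::tibble(ar = c(1.0, 1.45), ir_ar = c(3.0, 4.6)) |>
#'   classify_cohort()
#' @export
classify_cohort <- function(data, thresholds = risk_thresholds()) {
  check_column(data, "ar", "classify_cohort")
  check_column(data, "ir_ar", "classify_cohort")
  out <- tibble::as_tibble(data)
  out$ar_band <- classify_ar(out$ar, thresholds)
  out$irar_band <- classify_irar(out$ir_ar, thresholds)
  out
}
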