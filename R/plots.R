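#' Group means of an index with 95% confidence intervals
#'
#' Point-and-errorbar plot of a variable's group means, the layout used to
#' read off reference ranges and cut-offs from the group intervals. Raw or
#' ANCOVA-adjusted means can be shown.
#'
#' @param evaluation an [evaluate_case_control()] result.
#' @param variable variable to plot (default `"ar"`).
#' @param adjusted plot ANCOVA-adjusted means instead of raw means.
#' @return a ggplot object.
#' @export
plot_group_means <- function(evaluation, variable = "ar", adjusted = FALSE) {
  stopifnot(inherits(evaluation, "ar_evaluation"))
  d <- evaluation$group_summary |>
    dplyr::filter(.data$variable == !!variable)
  if (nrow(d) == 0L) {
    abort(sprintf("Variable `%s` not in the evaluation.", variable),
          class = "arindex_domain_error")
  }
  if (adjusted) {
    d <- d |>
      dplyr::mutate(mean = .data$adj_mean, ci_low = .data$adj_ci_low,
                    ci_high = .data$adj_ci_high)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = NULL, y = variable,
      title = sprintf("%s by group%s (mean, 95%% CI)", variable,
                      if (adjusted) ", age-adjusted" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Visualise the published risk-band ladder
#'
#' Shaded bands of the threshold system for the AR or IR_AR index, optionally
#' with observed index values overlaid as jittered points.
#'
#' @param thresholds a [risk_thresholds()].
#' @param index `"ar"` or `"irar"`.
#' @param values optional numeric vector of index values to overlay.
#' @return a ggplot object.
#' @export
plot_risk_bands <- function(thresholds = risk_thresholds(),
                            index = c("ar", "irar"), values = NULL) {
  index <- match.arg(index)
  if (index == "ar") {
    bands <- tibble::tibble(
      band = factor(ar_band_levels, levels = ar_band_levels),
      lo = c(-Inf, thresholds$ar_healthy_range[2], thresholds$ar_cutoffs),
      hi = c(thresholds$ar_healthy_range[2], thresholds$ar_cutoffs, Inf)
    )
    lab <- "AR index"
  } else {
    bands <- tibble::tibble(
      band = factor(irar_band_levels, levels = irar_band_levels),
      lo = c(-Inf, thresholds$irar_sensitive_range[2],
             thresholds$irar_mild_band[1], thresholds$irar_moderate_band[1],
             thresholds$irar_severe_band[1]),
      hi = c(thresholds$irar_sensitive_range[2],
             thresholds$irar_mild_band[1], thresholds$irar_moderate_band[1],
             thresholds$irar_severe_band[1], Inf)
    )
    lab <- "IR_AR index"
  }
  p <- ggplot2::ggplot(bands) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = 0, ymax = 1,
                   fill = .data$band),
      alpha = 0.6
    ) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    ggplot2::labs(x = lab, y = NULL, fill = "band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(values)) {
    p <- p + ggplot2::geom_jitter(
      data = tibble::tibble(x = values),
      ggplot2::aes(x = .data$x, y = 0.5), height = 0.3,
      inherit.aes = FALSE, alpha = 0.4, size = 0.8
    )
  }
  p
}

#' @method autoplot ar_evaluation
#' @export
autoplot.ar_evaluation <- function(object, variable = "ar",
                                   adjusted = FALSE, ...) {
  plot_group_means(object, variable, adjusted)
}

#' @method autoplot ar_corr
#' @export
autoplot.ar_corr <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
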