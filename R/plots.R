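# ggplot2 displays for the main result types.

#' Plot cumulative incidence by risk-score decile
#'
#' Dot plot of observed (Kaplan-Meier) incidence at the horizon per
#' decile, with the model-predicted means overlaid when present.
#'
#' @param groups Output of [group_cumulative_incidence()].
#' @param horizon Horizon used (for the axis label); optional.
#' @return A ggplot object.
#' @export
plot_decile_incidence <- function(groups, horizon = NULL) {
  lab <- if (is.null(horizon)) "Cumulative incidence" else
    sprintf("Cumulative incidence by %g years", horizon)
  p <- ggplot2::ggplot(groups, ggplot2::aes(x = factor(.data$group),
                                            y = .data$observed)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "Risk-score decile", y = lab)
  if (!all(is.na(groups$predicted))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$predicted),
                                 colour = "red3", size = 2)
  }
  p
}

#' Calibration plot of predicted versus observed incidence
#'
#' @param bins Output of [calibration_bins()].
#' @return A ggplot object with the identity line for reference.
#' @export
plot_calibration <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_predicted,
                                     y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed incidence (Kaplan-Meier)")
}

#' @describeIn decision_curve Plot net benefit against the threshold
#'   probability for every model and the treat-all/treat-none references.
#' @param object A `decision_curve`.
#' @param ... Unused.
#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pt, y = .data$net_benefit,
                                       colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.01, NA)) +
    ggplot2::labs(x = "Threshold probability",
                  y = sprintf("Net benefit (%g-year horizon)",
                              attr(object, "horizon")),
                  colour = NULL)
}

#' Plot a predicted-risk surface
#'
#' @param surface Output of [predicted_risk_surface()].
#' @return A ggplot object: one line per clinical-risk percentile across
#'   polygenic-score values.
#' @export
plot_risk_surface <- function(surface) {
  ggplot2::ggplot(surface,
                  ggplot2::aes(x = .data$ps_value, y = .data$probability,
                               colour = factor(.data$clinical_percentile))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Polygenic score (SD)",
                  y = "Predicted cumulative incidence",
                  colour = "Clinical-risk percentile")
}
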