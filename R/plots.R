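# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scaling curve
#'
#' Log-log plot of the apex-estimate spread versus side length, annotated
#' with the fitted power-law exponent; the dashed reference line has slope 1
#' (the straight-line model's forced scaling).
#'
#' @param object A `tc_scaling_curve` (from [scaling_curve()] or
#'   [null_scaling_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_scaling_curve <- function(object, ...) {
  fit <- fit_power_law(object$L, object$sigma_y)
  ref <- object$sigma_y[1L] / object$L[1L]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$sigma_y)) +
    ggplot2::geom_abline(
      intercept = log10(ref), slope = 1,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "side length L", y = expression(sigma[y]),
      title = sprintf(
        "Apex spread vs side length (fitted exponent %.2f)",
        fit$exponent
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot missing-angle predictions
#'
#' Mean predicted missing angle with a one-SD ribbon across side lengths;
#' the dashed line marks the Euclidean answer `180 - 2 theta0`.
#'
#' @param object A `tc_angle_curve` from [angle_stats_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_angle_curve <- function(object, ...) {
  th <- attr(object, "theta0_deg")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$mean_angle_deg)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_angle_deg - .data$sd_angle_deg,
        ymax = .data$mean_angle_deg + .data$sd_angle_deg
      ),
      fill = "#a6bddb", alpha = 0.5
    ) +
    ggplot2::geom_line(colour = "#045a8d") +
    ggplot2::geom_hline(
      yintercept = 180 - 2 * th,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "side length L", y = "missing angle (deg)",
      title = sprintf("Predicted missing angle, base angle %g deg", th)
    ) +
    ggplot2::theme_minimal()
}

#' Plot categorical response predictions
#'
#' Stacked proportions of the three response categories per question code.
#'
#' @param object A `tc_response_distribution` (from [predict_all()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_response_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("p_increase", "p_decrease", "p_same"),
    names_to = "category", values_to = "proportion",
    names_prefix = "p_"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$code, y = .data$proportion, fill = .data$category
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(increase = "#1b9e77", decrease = "#d95f02", same = "#7570b3")
    ) +
    ggplot2::labs(x = "question", y = "predicted proportion") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap exponent distribution
#'
#' Histogram of bootstrap scaling exponents with the median and 95%
#' interval; the dashed line marks slope 1, the straight-line prediction.
#'
#' @param object A `tc_scaling_fit` from [fit_scaling_exponent()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_scaling_fit <- function(object, ...) {
  d <- tibble::tibble(exponent = object$boot)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$exponent)) +
    ggplot2::geom_histogram(bins = 40, fill = "#74a9cf", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_exponent, colour = "#034e7b") +
    ggplot2::geom_vline(
      xintercept = object$ci,
      linetype = "dotted", colour = "#034e7b"
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "bootstrap exponent", y = "count",
      title = sprintf(
        "Scaling exponent: median %.2f [%.2f, %.2f]",
        object$median_exponent, object$ci[1L], object$ci[2L]
      )
    ) +
    ggplot2::theme_minimal()
}
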