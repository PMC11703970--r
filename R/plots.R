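#' Plot a decoding curve
#'
#' Classification accuracy as a function of decision-window length.
#'
#' @param object A [decoding_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoding_curve
#' @export
autoplot.decoding_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "decision window (s)", y = "accuracy",
      title = "Decoding curve"
    )
}

#' Plot the calibrated score distributions and decision boundary
#'
#' Target and non-target score-distribution means (solid), one-standard-
#' deviation bands (dashed), and the minimum-risk boundary per decision
#' window — the calibration picture of the Bayesian stopping model.
#'
#' @param object A `bds_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bds_model
#' @export
autoplot.bds_model <- function(object, ...) {
  td <- tidy(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(td, .data$time_s,
      value = .data$mean_target,
      lo = .data$mean_target - .data$sd_target,
      hi = .data$mean_target + .data$sd_target,
      which = "target"
    ),
    dplyr::transmute(td, .data$time_s,
      value = .data$mean_nontarget,
      lo = .data$mean_nontarget - .data$sd_nontarget,
      hi = .data$mean_nontarget + .data$sd_nontarget,
      which = "non-target"
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$which),
      alpha = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value, colour = .data$which)) +
    ggplot2::geom_line(
      data = dplyr::filter(td, is.finite(.data$eta)),
      ggplot2::aes(y = .data$eta),
      colour = "black", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "decision window (s)", y = "inner-product score",
      colour = NULL, fill = NULL,
      title = sprintf("Score model and decision boundary (zeta = %g)", object$zeta)
    )
}

#' Plot a hyper-parameter sweep as operating curves
#'
#' Accuracy-versus-time and precision-versus-time operating curves of a
#' stopping method as its hyper-parameter varies.
#'
#' @param object A `stopping_sweep` tibble (see [sweep_stopping()]).
#' @param metric y-axis metric: `"accuracy"` or `"precision"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stopping_sweep
#' @export
autoplot.stopping_sweep <- function(object, metric = c("accuracy", "precision"),
                                    ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$mean_stop_time, y = .data[[metric]], colour = .data$method
  )) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(size = .data$hyper), alpha = 0.6) +
    ggplot2::scale_size_continuous(trans = "log10") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "mean stopping time (s)", y = metric,
      title = sprintf("%s vs stopping time", metric)
    )
}

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot .data
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
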