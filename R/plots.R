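#' Plot SD time courses
#'
#' Mean +/- SEM SD value versus time, coloured by species and facetted by
#' AEF fraction when several are present.
#'
#' @param tc A [summarize_timecourse()] tibble.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_h, y = .data$sd_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$sd_mean - .data$sd_sem,
                   ymax = .data$sd_mean + .data$sd_sem),
      width = 4, na.rm = TRUE) +
    ggplot2::labs(x = "Time (h)", y = "SD of pixel brightness") +
    ggplot2::theme_minimal()
  if ("species" %in% names(tc)) {
    p <- p + ggplot2::aes(colour = .data$species, group = .data$species)
  }
  if ("aef_fraction" %in% names(tc) && length(unique(tc$aef_fraction)) > 1) {
    p <- p + ggplot2::facet_wrap(~aef_fraction, labeller = ggplot2::label_both)
  }
  p
}

#' Plot an endpoint dose-response panel
#'
#' Endpoint SD versus AEF fraction, replicates as points, mean as line,
#' coloured by species when present.
#'
#' @param dr A [dose_response()] tibble.
#' @return A ggplot object.
#' @export
plot_doseresponse <- function(dr) {
  p <- ggplot2::ggplot(dr, ggplot2::aes(x = .data$aef_fraction,
                                        y = .data$sd_value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "AEF fraction", y = "Endpoint SD") +
    ggplot2::theme_minimal()
  if ("species" %in% names(dr)) {
    p <- p + ggplot2::aes(colour = .data$species, group = .data$species)
  }
  p
}

#' @describeIn plot_timecourse autoplot method for sigmoid fits: data points
#'   with the fitted Boltzmann curve.
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(time_h = seq(min(object$data$time_h),
                                      max(object$data$time_h),
                                      length.out = 200))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$sd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$time_h, y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t50, linetype = "dashed") +
    ggplot2::labs(x = "Time (h)", y = "SD",
                  title = sprintf("t50 = %.1f h, lag = %.1f h",
                                  object$t50, object$lag_time)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_timecourse autoplot method for half-max fits: replicate
#'   points with the fitted 4PL curve on a linear AEF axis.
#' @export
autoplot.halfmax_fit <- function(object, ...) {
  grid <- tibble::tibble(aef_fraction = seq(min(object$data$aef_fraction),
                                            max(object$data$aef_fraction),
                                            length.out = 200))
  grid$fit <- predict(object, grid)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$aef_fraction, y = .data$sd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$aef_fraction, y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "AEF fraction", y = "Endpoint SD") +
    ggplot2::theme_minimal()
  if (!object$unidentifiable) {
    p <- p + ggplot2::geom_vline(xintercept = object$half_max_fraction,
                                 linetype = "dashed") +
      ggplot2::ggtitle(sprintf("half-max fraction = %.3f",
                               object$half_max_fraction))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
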