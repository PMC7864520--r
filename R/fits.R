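#' Fit a Boltzmann sigmoid to an aggregation time course
#'
#' Least-squares fit of the four-parameter Boltzmann sigmoid
#' \deqn{y(t) = baseline + \frac{plateau - baseline}{1 + e^{-slope (t - t50)}}}
#' to SD-versus-time data, the conventional description of nucleation-limited
#' amyloid growth. The lag time is derived as `t50 - 2/slope`, floored at 0.
#' A deterministic multistart grid over `t50` and `slope` feeds
#' [minpack.lm::nlsLM]; the lowest-RSS converged start wins.
#'
#' @param tc A data frame with columns `time_h` and `sd_mean` (a
#'   [summarize_timecourse()] output) or `time_h` and `sd_value`.
#' @param min_points Minimum number of time points required (default 5).
#' @return An object of class `sigmoid_fit` with elements `baseline`,
#'   `plateau`, `t50`, `slope`, `lag_time`, `rss`, `extrapolated` (TRUE when
#'   `t50` falls outside the observed time range) and `data`.
#' @examples
#' tt <- seq(0, 168, 24)
#' y <- 0.5 + 3.5 / (1 + exp(-0.1 * (tt - 72)))
#' fit_sigmoid(data.frame(time_h = tt, sd_mean = y))
#' @export
fit_sigmoid <- function(tc, min_points = 5L) {
  ycol <- if ("sd_mean" %in% names(tc)) "sd_mean" else "sd_value"
  if (!is.data.frame(tc) || !all(c("time_h", ycol) %in% names(tc))) {
    stop_input("`tc` must contain time_h and sd_mean/sd_value columns")
  }
  t <- tc$time_h; y <- tc[[ycol]]
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(unique(t)) < min_points) {
    stop_input("at least %d distinct time points are required", min_points)
  }
  rng <- range(y)
  span <- diff(rng)
  tspan <- diff(range(t))
  if (span <= .Machine$double.eps * max(1, abs(rng[2]))) {
    # flat series: plateau == baseline, no identifiable transition
    return(new_sigmoid_fit(baseline = rng[1], plateau = rng[2],
                           t50 = max(t) + tspan, slope = 1 / max(tspan, 1),
                           rss = 0, t = t, y = y, extrapolated = TRUE))
  }
  starts <- tidyr::expand_grid(
    t50 = quantile(t, c(0.25, 0.5, 0.75), names = FALSE),
    slope = c(0.02, 0.05, 0.1, 0.3)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + (plateau - baseline) / (1 + exp(-slope * (t - t50))),
        start = list(baseline = rng[1], plateau = rng[2],
                     t50 = starts$t50[i], slope = starts$slope[i]),
        lower = c(-Inf, -Inf, -10 * tspan, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop_fit("sigmoid fit failed to converge from any of %d starts", nrow(starts))
  }
  p <- as.list(coef(best$fit))
  if (p$plateau < p$baseline) {
    # re-express a descending fit in the canonical ascending orientation
    tmp <- p$baseline; p$baseline <- p$plateau; p$plateau <- tmp
    p$slope <- -p$slope
  }
  new_sigmoid_fit(baseline = p$baseline, plateau = p$plateau, t50 = p$t50,
                  slope = p$slope, rss = best$rss, t = t, y = y,
                  extrapolated = p$t50 < min(t) || p$t50 > max(t))
}

new_sigmoid_fit <- function(baseline, plateau, t50, slope, rss, t, y,
                            extrapolated) {
  structure(
    list(baseline = baseline, plateau = plateau, t50 = t50, slope = slope,
         lag_time = max(t50 - 2 / slope, 0), rss = rss,
         extrapolated = extrapolated,
         data = tibble::tibble(time_h = t, sd = y)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Boltzmann sigmoid fit\n")
  cat(sprintf("  baseline %.4g, plateau %.4g\n", x$baseline, x$plateau))
  cat(sprintf("  t50 %.4g h%s, slope %.4g /h, lag %.4g h\n",
              x$t50, if (x$extrapolated) " (extrapolated)" else "",
              x$slope, x$lag_time))
  cat(sprintf("  RSS %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h else newdata$time_h
  object$baseline + (object$plateau - object$baseline) /
    (1 + exp(-object$slope * (t - object$t50)))
}

#' Fit a rising four-parameter logistic dose-response curve
#'
#' Fits \deqn{y(x) = bottom + \frac{top - bottom}{1 + (half\_max / x)^{hill}}}
#' to endpoint SD versus AEF fraction. This is the EC50-style half-maximal
#' fit transposed to the seeding axis: `half_max_fraction` is the AEF
#' fraction producing a response halfway between `bottom` and `top`.
#' Deterministic multistart nonlinear least squares.
#'
#' @param dr A data frame with columns `aef_fraction` and `sd_value`
#'   (replicates as separate rows; a [dose_response()] output).
#' @param min_fractions Minimum distinct fractions required (default 4).
#' @return An object of class `halfmax_fit` with `bottom`, `top`,
#'   `half_max_fraction`, `hill`, `rss`, `unidentifiable` and `data`. For a
#'   constant response the half-max is flagged unidentifiable (`NA`).
#' @export
fit_half_max <- function(dr, min_fractions = 4L) {
  if (!is.data.frame(dr) || !all(c("aef_fraction", "sd_value") %in% names(dr))) {
    stop_input("`dr` must contain aef_fraction and sd_value columns")
  }
  x <- dr$aef_fraction; y <- dr$sd_value
  ok <- is.finite(x) & is.finite(y) & x >= 0
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < min_fractions) {
    stop_input("at least %d distinct AEF fractions are required", min_fractions)
  }
  rng <- range(y)
  if (diff(rng) <= 1e-10 * max(1, abs(rng[2]))) {
    return(structure(
      list(bottom = rng[1], top = rng[2], half_max_fraction = NA_real_,
           hill = NA_real_, rss = 0, unidentifiable = TRUE,
           data = tibble::tibble(aef_fraction = x, sd = y)),
      class = "halfmax_fit"
    ))
  }
  starts <- tidyr::expand_grid(
    half = c(0.15, 0.3, 0.6),
    hill = c(0.5, 1, 2, 4)
  )
  # x = 0 (vehicle control) is admitted with its 4PL limit, the bottom;
  # bottom itself is bounded at 0 because a brightness SD cannot be negative
  pl4 <- function(x, bottom, top, half, hill) {
    bottom + (top - bottom) *
      ifelse(x > 0, 1 / (1 + (half / x)^hill), 0)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ pl4(x, bottom, top, half, hill),
        start = list(bottom = max(rng[1], 0), top = rng[2],
                     half = starts$half[i], hill = starts$hill[i]),
        lower = c(0, 0, 1e-6, 0.05),
        upper = c(Inf, Inf, 100, 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop_fit("half-max fit failed to converge from any of %d starts", nrow(starts))
  }
  p <- as.list(coef(best$fit))
  structure(
    list(bottom = p$bottom, top = p$top, half_max_fraction = p$half,
         hill = p$hill, rss = best$rss, unidentifiable = FALSE,
         data = tibble::tibble(aef_fraction = x, sd = y)),
    class = "halfmax_fit"
  )
}

#' @export
print.halfmax_fit <- function(x, ...) {
  cat("Half-maximal (4PL) dose-response fit\n")
  if (x$unidentifiable) {
    cat("  constant response: half-max unidentifiable\n")
  } else {
    cat(sprintf("  bottom %.4g, top %.4g\n", x$bottom, x$top))
    cat(sprintf("  half-max fraction %.4g, hill %.4g, RSS %.4g\n",
                x$half_max_fraction, x$hill, x$rss))
  }
  invisible(x)
}

#' @export
predict.halfmax_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$aef_fraction else newdata$aef_fraction
  if (object$unidentifiable) return(rep(object$bottom, length(x)))
  object$bottom + (object$top - object$bottom) *
    ifelse(x > 0,
           1 / (1 + (object$half_max_fraction / x)^object$hill), 0)
}

#' Operational half-maximal dose of a fitted dose-response curve
#'
#' The dose at which the fitted curve crosses halfway between its predicted
#' responses at the two ends of the tested dose range. When the top plateau
#' is reached within the range this coincides with the 4PL
#' `half_max_fraction` parameter; when the top is extrapolated the
#' parameter rides a top/half/hill ridge and is poorly identified, while
#' the within-range crossing remains stable. This is the EC50 as an
#' experimentalist would read it off the plate.
#'
#' @param fit A `halfmax_fit` object.
#' @param x_range Dose range defining "minimal" and "maximal" response
#'   (default `c(0, 1)`, the AEF fraction scale).
#' @return The crossing dose (same units as `aef_fraction`), or `NA` for an
#'   unidentifiable fit.
#' @export
half_max_dose <- function(fit, x_range = c(0, 1)) {
  if (!inherits(fit, "halfmax_fit")) stop_input("`fit` must be a halfmax_fit")
  if (fit$unidentifiable) return(NA_real_)
  ends <- predict(fit, data.frame(aef_fraction = x_range))
  ystar <- mean(ends)
  r <- (fit$top - fit$bottom) / (ystar - fit$bottom) - 1
  if (!is.finite(r) || r <= 0) return(NA_real_)
  fit$half_max_fraction / r^(1 / fit$hill)
}

#' Tidy methods for fitted curves
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row
#' model summary.
#'
#' @param x A `sigmoid_fit` or `halfmax_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("baseline", "plateau", "t50", "slope", "lag_time"),
    estimate = c(x$baseline, x$plateau, x$t50, x$slope, x$lag_time)
  )
}

#' @rdname tidiers
#' @export
tidy.halfmax_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "half_max_fraction", "hill"),
    estimate = c(x$bottom, x$top, x$half_max_fraction, x$hill)
  )
}

#' @rdname tidiers
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), extrapolated = x$extrapolated)
}

#' @rdname tidiers
#' @export
glance.halfmax_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data),
                 unidentifiable = x$unidentifiable)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
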