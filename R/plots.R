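#' @exportS3Method ggplot2::autoplot
autoplot.sbf_output <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "output",
                  title = if (!is.null(cfg$criterion))
                    sprintf("SBF output, criterion %g s", cfg$criterion)
                  else "SBF output") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gaussian_fit <- function(object, ...) {
  grid <- tibble(t = seq(object$window[1], object$window[2],
                         length.out = 400))
  grid$value <- object$amplitude *
    exp(-(grid$t - object$center)^2 / (2 * object$sigma^2))
  ggplot2::ggplot(object$envelope,
                  ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "envelope",
                  subtitle = sprintf("sigma = %.3g s, r2 = %.3f",
                                     object$sigma, object$r2)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.scalar_regression <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$criterion, y = .data$sigma)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "criterion time (s)", y = "output width (s)",
                  subtitle = sprintf("slope = %.4g +/- %.2g, r2 = %.3f",
                                     object$slope, object$slope_se,
                                     object$r2)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.superposition <- function(object, ...) {
  ggplot2::ggplot(object$rescaled,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data$criterion))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "t / criterion", y = "normalised output",
                  colour = "criterion (s)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sbf_experiment <- function(object, ...) {
  if (!is.null(object$traces)) {
    ggplot2::ggplot(object$traces,
                    ggplot2::aes(x = .data$t, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~criterion, scales = "free_x") +
      ggplot2::labs(x = "time (s)", y = "output") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$widths,
                    ggplot2::aes(x = .data$criterion, y = .data$sigma,
                                 colour = factor(.data$level))) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4) +
      ggplot2::labs(x = "criterion time (s)", y = "fitted sigma (s)",
                    colour = "noise level") +
      ggplot2::theme_minimal()
  }
}
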