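#' Upper envelope of an oscillatory output trace
#'
#' Extracts the local maxima of `|value|` (plateaus tie-broken to the
#' leftmost point): the slowly varying hull that the Gaussian is fitted to.
#'
#' @param trace An `sbf_output` or any tibble with columns `t`, `value`.
#' @return A tibble with columns `t`, `value` (absolute values at the local
#'   maxima).
#' @export
upper_envelope <- function(trace) {
  v <- abs(trace$value)
  n <- length(v)
  if (n < 3) return(tibble(t = numeric(0), value = numeric(0)))
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  idx <- i[is_max]
  tibble(t = trace$t[idx], value = v[idx])
}

#' Amplitude envelope of a noisy output burst
#'
#' Under memory noise the output is a burst of interfering kernels whose
#' instantaneous amplitude fluctuates strongly (the carrier phases of the
#' per-sample kernels are incoherent), so the hull of raw local maxima is a
#' high-variance envelope estimate. `burst_envelope()` computes the standard
#' root-mean-square amplitude envelope instead: the squared signal is
#' smoothed by a moving average of width `smooth` seconds and the square
#' root taken. When the trace carries per-batch partial sums (see
#' `keep_batches` in [memory_noise_output()] and [sbf_output()]) the power
#' is additionally averaged over the independent batches, reducing the
#' envelope variance by the batch count at no extra simulation cost.
#'
#' @param trace An `sbf_output` (or tibble with `t`, `value`).
#' @param smooth Smoothing window in seconds; defaults to a quarter of the
#'   central 68% spread of the signal power.
#' @return A tibble with columns `t`, `value` (the envelope), suitable for
#'   [fit_gaussian()].
#' @export
burst_envelope <- function(trace, smooth = NULL) {
  bm <- attr(trace, "batch_values")
  power <- if (!is.null(bm)) rowMeans(bm^2) else trace$value^2
  dt <- median(diff(trace$t))
  if (is.null(smooth)) {
    w <- sqrt(sum(power * (trace$t - sum(power * trace$t) / sum(power))^2) /
                sum(power))
    smooth <- w / 2
  }
  k <- max(3L, as.integer(round(smooth / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(power, rep(1 / k, k), sides = 2)
  keep <- !is.na(sm)
  tibble(t = trace$t[keep], value = sqrt(pmax(as.numeric(sm[keep]), 0)))
}

#' Fit a Gaussian to the envelope of an output trace
#'
#' Least-squares fit of `A exp(-(t - mu)^2 / (2 sigma^2))` to the upper
#' envelope (local maxima of `|value|`) restricted to `window`. When the
#' trace is non-oscillatory (fewer than 5 interior maxima) all samples in
#' the window are used instead. Fitting uses Levenberg-Marquardt least
#' squares; a fitted centre outside the window is treated as a failed fit.
#'
#' @param trace An `sbf_output` (or tibble with `t`, `value`).
#' @param window Time window `c(lo, hi)` containing a single dominant peak;
#'   defaults to the whole trace.
#' @param offset Also fit a non-negative constant baseline
#'   (`A exp(...) + b`). Useful for burst envelopes, which ride on a small
#'   incoherent floor contributed by the kernel tails.
#' @param envelope `"maxima"` extracts the local-maxima hull of `|value|`
#'   first, `"points"` fits every sample as-is (appropriate when `trace` is
#'   already an envelope, e.g. from [burst_envelope()]), and the default
#'   `"auto"` picks `"maxima"` exactly when the signal takes negative values
#'   (i.e. is an oscillating trace rather than an envelope).
#' @return An object of class `gaussian_fit` with fields `amplitude`,
#'   `center`, `sigma`, `r2`, the envelope points and the window. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' bank <- oscillator_bank(5.5, 11.5, 200)
#' out <- memory_noise_output(bank, 30,
#'   mem_noise = noise_spec("normal", 0.01, 200, seed = 1))
#' glance(fit_gaussian(out))
#' @export
fit_gaussian <- function(trace, window = NULL, offset = FALSE,
                         envelope = c("auto", "maxima", "points")) {
  envelope <- match.arg(envelope)
  window <- window %||% range(trace$t)
  inside <- trace$t >= window[1] & trace$t <= window[2]
  sub <- trace[inside, , drop = FALSE]
  if (nrow(sub) < 5)
    abort("fewer than 5 samples in the fitting window",
          class = "sbf_insufficient_data")
  if (envelope == "auto")
    envelope <- if (any(sub$value < 0)) "maxima" else "points"
  env <- if (envelope == "maxima") upper_envelope(sub) else
    tibble(t = sub$t, value = abs(sub$value))
  if (nrow(env) < 5) env <- tibble(t = sub$t, value = abs(sub$value))
  if (nrow(env) < 5)
    abort("fewer than 5 envelope points in the fitting window",
          class = "sbf_insufficient_data")

  a0 <- max(env$value)
  # start values from the half-maximum crossings: robust for any single bump
  hm <- tryCatch(halfmax_interval(env), error = function(e) NULL)
  if (!is.null(hm)) {
    mu0 <- mean(hm)
    s0 <- diff(hm) / (2 * sqrt(2 * log(2)))
  } else {
    mu0 <- env$t[which.max(env$value)]
    s0 <- sqrt(sum(env$value * (env$t - mu0)^2) / sum(env$value))
  }
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(window) / 6
  s0 <- s0 * 1.1   # never start exactly at the optimum (singular Jacobian)
  mu0 <- min(max(mu0, window[1]), window[2])
  # minpack scales parameters by magnitude: an exactly-zero start is singular
  if (abs(mu0) < 1e-3 * s0) mu0 <- mu0 + 1e-3 * s0

  span <- diff(window)
  try_fit <- function(mu_start, s_start) {
    if (offset) {
      minpack.lm::nlsLM(
        value ~ A * exp(-(t - mu)^2 / (2 * s^2)) + b,
        data = env,
        start = list(A = a0, mu = mu_start, s = s_start, b = min(env$value)),
        lower = c(A = 0, mu = window[1], s = 1e-12, b = 0),
        upper = c(A = Inf, mu = window[2], s = 2 * span, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        value ~ A * exp(-(t - mu)^2 / (2 * s^2)),
        data = env,
        start = list(A = a0, mu = mu_start, s = s_start),
        lower = c(A = 0, mu = window[1], s = 1e-12),
        upper = c(A = Inf, mu = window[2], s = 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }
  # the Levenberg-Marquardt path can hit a singular parameter scaling for
  # unlucky starts; retry from a few deterministic perturbations
  fit <- NULL
  last_err <- NULL
  for (off in c(0, 0.15, -0.15, 0.4)) {
    mu_try <- min(max(mu0 + off * s0, window[1]), window[2])
    fit <- tryCatch(try_fit(mu_try, s0 * (1 + abs(off))),
                    error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    abort(paste0("Gaussian fit did not converge: ",
                 conditionMessage(last_err)),
          class = "sbf_fit_error")
  est <- coef(fit)
  resid <- env$value - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((env$value - mean(env$value))^2)
  if (est[["mu"]] <= window[1] + 1e-9 * span ||
      est[["mu"]] >= window[2] - 1e-9 * span)
    abort(sprintf(
      "fitted centre %.3f pinned at the window boundary [%.3f, %.3f]",
      est[["mu"]], window[1], window[2]), class = "sbf_fit_error")

  structure(
    list(amplitude = est[["A"]], center = est[["mu"]], sigma = est[["s"]],
         offset = if (offset) est[["b"]] else 0,
         r2 = r2, envelope = env, window = window, residuals = resid),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> A = %.4g, center = %.4f s, sigma = %.4g s, r2 = %.4f\n",
    x$amplitude, x$center, x$sigma, x$r2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("amplitude", "center", "sigma"),
         estimate = c(x$amplitude, x$center, x$sigma))
}

#' @exportS3Method generics::glance
glance.gaussian_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, center = x$center, sigma = x$sigma,
         r2 = x$r2, n_envelope = nrow(x$envelope))
}

#' Half-maximum width measured directly from a trace
#'
#' Empirical counterpart of [noiseless_width()]: finds the peak of the upper
#' envelope and the interpolated times at which the envelope falls to half
#' the peak on each side.
#'
#' @param trace An `sbf_output` (or tibble with `t`, `value`).
#' @return Full width at half maximum (s).
#' @export
trace_halfmax_width <- function(trace) {
  env <- upper_envelope(trace)
  if (nrow(env) < 5) env <- tibble(t = trace$t, value = abs(trace$value))
  diff(halfmax_interval(env))
}

# interpolated times at which a single-bump envelope crosses half its peak
halfmax_interval <- function(env) {
  i_pk <- which.max(env$value)
  half <- env$value[i_pk] / 2
  left <- env[seq_len(i_pk), ]
  right <- env[i_pk:nrow(env), ]
  below_l <- which(left$value <= half)
  below_r <- which(right$value <= half)
  if (length(below_l) == 0 || length(below_r) == 0)
    abort("envelope does not fall to half maximum inside the trace",
          class = "sbf_numerical_error")
  iL <- max(below_l)
  tL <- approx(left$value[c(iL, iL + 1)], left$t[c(iL, iL + 1)],
               xout = half)$y
  iR <- min(below_r)
  tR <- approx(right$value[c(iR - 1, iR)], right$t[c(iR - 1, iR)],
               xout = half)$y
  c(tL, tR)
}

#' Width-versus-criterion scalar regression
#'
#' Ordinary least squares of fitted output width on criterion time: the
#' scalar property of interval timing corresponds to a positive slope with
#' near-proportional widths, while the noiseless model yields slope ~ 0.
#'
#' @param fits Either a tibble with columns `criterion` and `sigma` (widths
#'   in seconds) or a list of `gaussian_fit` objects accompanied by
#'   `criteria`.
#' @param criteria Criterion times (s) matching `fits` when `fits` is a list.
#' @return A `scalar_regression` object wrapping the `lm` fit, with fields
#'   `slope`, `slope_se`, `intercept`, `r2` and the points. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
width_vs_criterion <- function(fits, criteria = NULL) {
  points <- if (inherits(fits, "data.frame")) {
    tibble(criterion = fits$criterion, sigma = fits$sigma)
  } else {
    stopifnot(!is.null(criteria), length(fits) == length(criteria))
    tibble(criterion = as.numeric(criteria),
           sigma = purrr::map_dbl(fits, "sigma"))
  }
  if (nrow(points) < 3)
    abort("at least 3 (criterion, width) points are required",
          class = "sbf_config_error")
  model <- lm(sigma ~ criterion, data = points)
  sm <- summary(model)
  structure(
    list(model = model, points = points,
         slope = unname(coef(model)[2]),
         slope_se = sm$coefficients["criterion", "Std. Error"],
         intercept = unname(coef(model)[1]),
         r2 = sm$r.squared),
    class = "scalar_regression"
  )
}

#' @export
print.scalar_regression <- function(x, ...) {
  cat(sprintf(
    "<scalar_regression> slope = %.4g +/- %.2g s/s, intercept = %.4g s, r2 = %.4f (%d criteria)\n",
    x$slope, x$slope_se, x$intercept, x$r2, nrow(x$points)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scalar_regression <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(sm[, "Estimate"]),
         std.error = unname(sm[, "Std. Error"]),
         statistic = unname(sm[, "t value"]),
         p.value = unname(sm[, "Pr(>|t|)"]))
}

#' @exportS3Method generics::glance
glance.scalar_regression <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
         r2 = x$r2, n = nrow(x$points))
}

#' Superposition (timescale-invariance) report
#'
#' Rescales each trace by its criterion time (`t -> t / c`) and its maximum
#' (`value -> value / max`), interpolates all traces onto a common
#' relative-time grid, and reports the maximum pairwise RMS difference.
#' Scalar-compliant responses superimpose (small RMS); constant-width
#' responses do not.
#'
#' @param traces List of `sbf_output` objects.
#' @param criteria Criterion times; defaults to each trace's recorded
#'   criterion.
#' @param n_grid Number of points of the common relative-time grid.
#' @return A list of class `superposition`: `rescaled` (long tibble of
#'   normalised traces), `rms` (pairwise matrix) and `max_rms`.
#' @export
superpose <- function(traces, criteria = NULL, n_grid = 512) {
  stopifnot(length(traces) >= 2)
  criteria <- criteria %||% purrr::map_dbl(traces, function(tr)
    attr(tr, "config")$criterion)
  rel <- purrr::map2(traces, criteria, function(tr, c) {
    tibble(x = tr$t / c, y = tr$value / max(tr$value))
  })
  lo <- max(purrr::map_dbl(rel, ~ min(.x$x)))
  hi <- min(purrr::map_dbl(rel, ~ max(.x$x)))
  if (lo >= hi)
    abort("traces have no common relative-time support",
          class = "sbf_alignment_error")
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(rel, function(r) approx(r$x, r$y, xout = grid)$y,
                numeric(n_grid))
  k <- length(traces)
  rms <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rms[i, j] <- rms[j, i] <- sqrt(mean((mat[, i] - mat[, j])^2))
  }
  rescaled <- purrr::imap_dfr(rel, function(r, i)
    dplyr::mutate(r, trace = i, criterion = criteria[[i]]))
  structure(
    list(rescaled = rescaled, grid = grid, rms = rms, max_rms = max(rms)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d traces, max pairwise RMS = %.4g\n",
              ncol(x$rms), x$max_rms))
  invisible(x)
}
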