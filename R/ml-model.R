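#' Parameters of the dimensionless Morris-Lecar neuron
#'
#' A two-variable conductance-based oscillator: membrane potential `x1` driven
#' by an instantaneous calcium current, a delayed-rectifier potassium current
#' gated by the slow activation `x2`, a leak, and a bias current `i0`.
#' All quantities are dimensionless. The defaults are the standard constants
#' of the dimensionless formulation: reversal potentials `e_ca = 1.0`,
#' `e_k = -0.7`, `e_l = -0.5`; activation-curve parameters `v1 = -0.01`,
#' `v2 = 0.15`, `v3 = 0.1`, `v4 = 0.145`; conductances `g_k = 2.0`,
#' `g_l = 0.5`; potassium rate scale `xi = 1/3`.
#'
#' The calcium conductance selects the excitability class: `type = "type1"`
#' sets `g_ca = 1.0` (firing onset at arbitrarily low rate, oscillatory for
#' bias currents in roughly (0.083, 0.242)); `type = "type2"` sets
#' `g_ca = 0.5` (onset at finite rate via a Hopf bifurcation, membrane
#' potential close to a cosine waveform). Type 2 is the default regime for
#' SBF simulations.
#'
#' @param type Regime preset, `"type2"` (default) or `"type1"`.
#' @param i0 Bias current.
#' @param g_ca Calcium conductance; overrides the preset when given.
#' @param g_k,g_l,e_ca,e_k,e_l,v1,v2,v3,v4,xi Remaining constants; override
#'   the defaults when given.
#' @return An object of class `ml_params`.
#' @examples
#' ml_params("type2", i0 = 0.2)
#' @export
ml_params <- function(type = c("type2", "type1"), i0 = 0, g_ca = NULL,
                      g_k = 2.0, g_l = 0.5, e_ca = 1.0, e_k = -0.7,
                      e_l = -0.5, v1 = -0.01, v2 = 0.15, v3 = 0.1,
                      v4 = 0.145, xi = 1 / 3) {
  type <- match.arg(type)
  g_ca <- g_ca %||% switch(type, type1 = 1.0, type2 = 0.5)
  structure(
    list(g_ca = g_ca, g_k = g_k, g_l = g_l, e_ca = e_ca, e_k = e_k,
         e_l = e_l, v1 = v1, v2 = v2, v3 = v3, v4 = v4, xi = xi,
         i0 = i0, type = type),
    class = "ml_params"
  )
}

#' @export
print.ml_params <- function(x, ...) {
  cat(sprintf("<ml_params> %s: g_ca = %g, g_k = %g, g_l = %g, i0 = %g\n",
              x$type, x$g_ca, x$g_k, x$g_l, x$i0))
  invisible(x)
}

# parameter vector in the order the C++ integrator expects
ml_par_vector <- function(params) {
  with(params, c(g_ca, g_k, g_l, e_ca, e_k, e_l, v1, v2, v3, v4, xi, i0))
}

#' Morris-Lecar steady-state activation curves
#'
#' `ml_m_inf()` is the instantaneous calcium activation, `ml_w_inf()` the
#' potassium activation target and `ml_lambda0()` its voltage-dependent rate.
#'
#' @param x1 Membrane potential.
#' @param params An [ml_params()] object.
#' @return Numeric vector.
#' @export
ml_m_inf <- function(x1, params) (1 + tanh((x1 - params$v1) / params$v2)) / 2

#' @rdname ml_m_inf
#' @export
ml_w_inf <- function(x1, params) (1 + tanh((x1 - params$v3) / params$v4)) / 2

#' @rdname ml_m_inf
#' @export
ml_lambda0 <- function(x1, params) cosh((x1 - params$v3) / (2 * params$v4))

#' Morris-Lecar vector field
#'
#' The right-hand side of the dimensionless Morris-Lecar system:
#' `dx1 = -I_Ca - I_K - I_L + i0` with `I_Ca = g_ca * m_inf(x1) * (x1 - e_ca)`,
#' `I_K = g_k * x2 * (x1 - e_k)`, `I_L = g_l * (x1 - e_l)`, and
#' `dx2 = xi * lambda0(x1) * (w_inf(x1) - x2)`.
#'
#' @param state Numeric vector `c(x1, x2)`.
#' @param params An [ml_params()] object.
#' @return Numeric vector `c(dx1, dx2)`.
#' @export
ml_derivatives <- function(state, params) {
  x1 <- state[[1]]; x2 <- state[[2]]
  dx1 <- -params$g_ca * ml_m_inf(x1, params) * (x1 - params$e_ca) -
    params$g_k * x2 * (x1 - params$e_k) -
    params$g_l * (x1 - params$e_l) + params$i0
  dx2 <- params$xi * ml_lambda0(x1, params) * (ml_w_inf(x1, params) - x2)
  c(dx1, dx2)
}

#' Integrate the Morris-Lecar system
#'
#' Fixed-step classical 4th-order Runge-Kutta integration on a uniform grid.
#' Deterministic and reproducible; the default step is far below the
#' oscillation period (the limit cycles of both regimes have periods of
#' roughly 6-20 dimensionless time units, so `dt = 0.025` gives several
#' hundred steps per period).
#'
#' @param params An [ml_params()] object (including the bias current `i0`).
#' @param t_end End time (dimensionless, > 0).
#' @param dt Step size (> 0).
#' @param init Initial state `c(x1, x2)`.
#' @param keep_every Store every `keep_every`-th step (thinning only affects
#'   storage, not accuracy).
#' @return An `ml_trace`: a tibble with columns `t`, `x1`, `x2` and
#'   attributes `dt` and `params`.
#' @examples
#' tr <- integrate_ml(ml_params("type2", i0 = 0.22), t_end = 200, dt = 0.05)
#' measure_period(tr)
#' @export
integrate_ml <- function(params, t_end, dt = 0.025,
                         init = c(-0.3, 0.1), keep_every = 1L) {
  stopifnot(inherits(params, "ml_params"))
  if (!(t_end > 0) || !(dt > 0))
    abort("`t_end` and `dt` must be positive", class = "sbf_config_error")
  n_steps <- max(1L, as.integer(round(t_end / dt)))
  out <- tryCatch(
    ml_rk4_cpp(ml_par_vector(params), init[[1]], init[[2]], dt, n_steps,
               as.integer(keep_every)),
    error = function(e) {
      abort(paste0("Morris-Lecar integration failed: ", conditionMessage(e)),
            class = "sbf_integration_error")
    }
  )
  structure(
    tibble(t = out$t, x1 = out$x1, x2 = out$x2),
    dt = dt * keep_every, params = params,
    class = c("ml_trace", class(tibble())))
}

#' Measure the oscillation period of a trace
#'
#' The period is the mean spacing of upward crossings of the trace mean
#' (sub-step accuracy by linear interpolation), after discarding an initial
#' transient: the first `transient_frac` of the trace or five estimated
#' periods, whichever is longer. The mean-crossing criterion is robust for
#' both spike-like (Type 1) and near-sinusoidal (Type 2) waveforms.
#'
#' @param trace An `ml_trace` from [integrate_ml()], or any tibble with
#'   columns `t` and `x1` on a uniform grid.
#' @param transient_frac Fraction of the trace discarded as transient.
#' @param min_amplitude Peak-to-peak amplitude below which the trace is
#'   declared non-oscillating.
#' @return A one-row tibble with `period`, `cv` (coefficient of variation of
#'   the crossing spacings) and `n_cycles`.
#' @export
measure_period <- function(trace, transient_frac = 0.2, min_amplitude = 0.02) {
  est <- period_from_window(trace, transient_frac, min_amplitude)
  # re-discard using the first estimate so that at least 5 periods are dropped
  span <- diff(range(trace$t))
  frac <- max(transient_frac, min(0.6, 5 * est$period / span))
  if (frac > transient_frac) est <- period_from_window(trace, frac, min_amplitude)
  tibble(period = est$period, cv = est$cv, n_cycles = est$n_cycles)
}

period_from_window <- function(trace, frac, min_amplitude) {
  keep <- trace$t >= frac * max(trace$t)
  t <- trace$t[keep]; x <- trace$x1[keep]
  if (diff(range(x)) < min_amplitude)
    abort("trace is not oscillating (amplitude below threshold)",
          class = "sbf_not_oscillating")
  cross <- crossing_times(t, x, mean(x))
  if (length(cross) < 2)
    abort("trace is not oscillating (fewer than 2 mean crossings)",
          class = "sbf_not_oscillating")
  sp <- diff(cross)
  list(period = mean(sp),
       cv = if (length(sp) > 1) sd(sp) / mean(sp) else 0,
       n_cycles = length(sp))
}

# times of upward crossings of `threshold`, linearly interpolated
crossing_times <- function(t, x, threshold) {
  n <- length(x)
  i <- which(x[-n] < threshold & x[-1] >= threshold)
  if (length(i) == 0) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (threshold - x[i]) / (x[i + 1] - x[i])
}

# TRUE if the system sustains a limit cycle at this bias current
ml_oscillates <- function(params, i0 = NULL, t_end = 600, dt = 0.05,
                          min_amplitude = 0.02) {
  if (!is.null(i0)) params$i0 <- i0
  tr <- integrate_ml(params, t_end, dt)
  ok <- tryCatch(
    measure_period(tr, min_amplitude = min_amplitude)$n_cycles >= 3,
    sbf_not_oscillating = function(e) FALSE
  )
  isTRUE(ok)
}

#' Locate the oscillatory bias-current range
#'
#' Scans a grid of bias currents for sustained limit-cycle oscillation
#' (post-transient mean-crossing cycles with non-vanishing amplitude) and
#' refines each edge of the detected contiguous range by bisection.
#' For the Type 1 preset (`g_ca = 1.0`) the range brackets (0.083, 0.242);
#' for Type 2 (`g_ca = 0.5`) it is determined empirically.
#'
#' @param params An [ml_params()] object; its `i0` is ignored.
#' @param i0_grid Increasing grid of bias currents spanning the regime.
#' @param refine Number of bisection steps per edge.
#' @param t_end,dt Integration horizon and step for the oscillation test.
#' @return A one-row tibble with `i0_min` and `i0_max`.
#' @export
find_oscillatory_range <- function(params, i0_grid, refine = 12,
                                   t_end = 600, dt = 0.05) {
  stopifnot(inherits(params, "ml_params"))
  i0_grid <- sort(i0_grid)
  osc <- vapply(i0_grid, function(i0) ml_oscillates(params, i0, t_end, dt),
                logical(1))
  if (!any(osc))
    abort("no oscillatory point on the bias-current grid",
          class = "sbf_empty_range")
  idx <- which(osc)
  lo <- i0_grid[idx[1]]; hi <- i0_grid[idx[length(idx)]]
  bisect_edge <- function(out, inside) {
    for (k in seq_len(refine)) {
      mid <- (out + inside) / 2
      if (ml_oscillates(params, mid, t_end, dt)) inside <- mid else out <- mid
    }
    inside
  }
  if (idx[1] > 1) lo <- bisect_edge(i0_grid[idx[1] - 1], lo)
  if (idx[length(idx)] < length(i0_grid))
    hi <- bisect_edge(i0_grid[idx[length(idx)] + 1], hi)
  tibble(i0_min = lo, i0_max = hi)
}

# dimensionless firing rate (cycles per unit time) at bias current i0
ml_rate <- function(params, i0, t_end = 500, dt = 0.025) {
  params$i0 <- i0
  tr <- integrate_ml(params, t_end, dt)
  1 / measure_period(tr)$period
}

#' Calibrate a Morris-Lecar neuron to a target firing rate in Hz
#'
#' Dimensionless Morris-Lecar time is mapped to seconds through a
#' `time_scale` (seconds per dimensionless unit), so a neuron with
#' dimensionless rate `r` fires at `r / time_scale` Hz. The bias current is
#' adjusted by monotone bisection on the measured rate until the realised
#' rate matches `target_f` within `tol`. If the target is unattainable at the
#' given `time_scale`, the time scale itself is adjusted at the nearest
#' attainable rate (and the fallback is flagged in the result).
#'
#' @param params An [ml_params()] object.
#' @param target_f Target firing rate in Hz.
#' @param search_range Bias-current interval `c(lo, hi)` inside the
#'   oscillatory regime.
#' @param time_scale Seconds per dimensionless time unit. When `NULL`, the
#'   time scale is chosen so that the range-midpoint rate maps to `target_f`.
#' @param tol Relative rate tolerance (default 0.5%).
#' @param t_end,dt Integration horizon and step per rate measurement.
#' @param max_iter Bisection iteration cap.
#' @return A one-row tibble with `i0`, `time_scale`, `rate` (dimensionless),
#'   `f_realized` (Hz), `rel_err` and `rescaled` (TRUE if the time-scale
#'   fallback was used).
#' @export
calibrate_frequency <- function(params, target_f, search_range,
                                time_scale = NULL, tol = 0.005,
                                t_end = 500, dt = 0.025, max_iter = 40) {
  stopifnot(inherits(params, "ml_params"), target_f > 0)
  lo <- search_range[[1]]; hi <- search_range[[2]]
  r_lo <- tryCatch(ml_rate(params, lo, t_end, dt), sbf_not_oscillating =
                     function(e) NA_real_)
  r_hi <- tryCatch(ml_rate(params, hi, t_end, dt), sbf_not_oscillating =
                     function(e) NA_real_)
  if (is.na(r_lo) || is.na(r_hi))
    abort("`search_range` must lie inside the oscillatory regime",
          class = "sbf_calibration_error")
  if (is.null(time_scale)) {
    r_mid <- ml_rate(params, (lo + hi) / 2, t_end, dt)
    time_scale <- r_mid / target_f
  }
  r_target <- target_f * time_scale
  rescaled <- FALSE
  if (r_target < min(r_lo, r_hi) || r_target > max(r_lo, r_hi)) {
    # unattainable at this time scale: pin i0 at the nearer edge and rescale
    rescaled <- TRUE
    at_hi <- abs(r_hi - r_target) < abs(r_lo - r_target)
    i0 <- if (at_hi) hi else lo
    rate <- if (at_hi) r_hi else r_lo
    time_scale <- rate / target_f
  } else {
    for (k in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      r_mid <- ml_rate(params, mid, t_end, dt)
      if (abs(r_mid - r_target) / r_target < tol / 5) break
      if (xor(r_mid > r_target, r_hi > r_lo)) lo <- mid else hi <- mid
    }
    i0 <- mid
    rate <- r_mid
  }
  f_real <- rate / time_scale
  rel_err <- abs(f_real - target_f) / target_f
  if (rel_err > tol)
    abort(sprintf("calibration failed: realised %.4f Hz vs target %.4f Hz",
                  f_real, target_f), class = "sbf_calibration_error")
  tibble(i0 = i0, time_scale = time_scale, rate = rate,
         f_realized = f_real, rel_err = rel_err, rescaled = rescaled)
}

#' Read and write Morris-Lecar parameters as YAML
#'
#' @param params An [ml_params()] object.
#' @param path File path.
#' @return `read_ml_params()` returns an [ml_params()] object;
#'   `write_ml_params()` returns `path` invisibly.
#' @export
write_ml_params <- function(params, path) {
  stopifnot(inherits(params, "ml_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_ml_params
#' @export
read_ml_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(ml_params, y[setdiff(names(y), "type")] |>
            (\(x) c(list(type = y$type), x))())
}
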