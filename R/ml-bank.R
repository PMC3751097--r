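#' Calibrate a bank of Morris-Lecar neurons to a frequency grid
#'
#' Builds the biophysical time base of the SBF model: one Type 2 (or Type 1)
#' Morris-Lecar neuron per frequency of the bank's grid. A single bank-wide
#' `time_scale` (seconds per dimensionless time unit) is chosen from the
#' measured dimensionless rate span of the oscillatory regime so that the
#' whole Hz range is attainable, and each neuron's bias current is then set
#' by monotone bisection until its realised rate matches its target within
#' `tol`. One limit-cycle period per neuron is stored as an
#' amplitude-normalised waveform (phase zero at the membrane-potential
#' maximum), from which oscillator states at arbitrary times are read out by
#' periodic phase lookup; this is exact for a deterministic limit cycle.
#'
#' At `t = 0` every neuron starts at its potential maximum (all phases
#' aligned), mirroring the trial-start reset of the oscillator block.
#'
#' @param bank An [oscillator_bank()] giving the target Hz grid.
#' @param params Base [ml_params()]; Type 2 by default.
#' @param tol Relative rate tolerance per neuron (default 0.5%).
#' @param margin Fraction of the oscillatory bias-current range kept clear at
#'   each edge when placing calibration targets.
#' @param n_wave Samples per stored limit-cycle waveform.
#' @param dt Integration step for calibration and waveform extraction.
#' @param i0_scan Coarse bias-current grid used to locate the oscillatory
#'   regime.
#' @return An object of class `ml_bank`: the bank spec, base parameters, the
#'   bank-wide `time_scale`, a per-neuron calibration table (`oscillator`,
#'   `f_target`, `i0`, `rate`, `f_realized`, `rel_err`) and the waveform
#'   matrix.
#' @examples
#' \donttest{
#' mlb <- calibrate_ml_bank(oscillator_bank(5.5, 11.5, 20))
#' mlb$table
#' }
#' @export
calibrate_ml_bank <- function(bank, params = ml_params("type2"),
                              tol = 0.005, margin = 0.03, n_wave = 2048L,
                              dt = 0.025, i0_scan = seq(0.05, 0.45, by = 0.02)) {
  stopifnot(inherits(bank, "oscillator_bank"), inherits(params, "ml_params"))
  freqs <- frequency_grid(bank)

  rng <- find_oscillatory_range(params, i0_scan, refine = 10, dt = dt)
  span <- rng$i0_max - rng$i0_min
  i0_lo <- rng$i0_min + margin * span
  i0_hi <- rng$i0_max - margin * span

  # coarse monotone rate curve for warm-starting the per-neuron bisection
  curve_i0 <- seq(i0_lo, i0_hi, length.out = 40)
  curve_r <- vapply(curve_i0, function(i0) ml_rate(params, i0, dt = dt),
                    numeric(1))
  if (any(diff(curve_r) <= 0))
    warn("rate vs bias current is not strictly monotone on the scan grid")
  r_lo <- curve_r[1]; r_hi <- curve_r[length(curve_r)]

  # one bank-wide time scale mapping the Hz range into the attainable
  # dimensionless rate span (geometric-mean centring); per-neuron rescaling
  # only if the span cannot cover the range
  time_scale <- sqrt(r_lo * r_hi) / sqrt(bank$f1 * bank$f2)
  if (bank$f2 * time_scale > r_hi || bank$f1 * time_scale < r_lo) {
    warn("Hz range not coverable by a single time scale; per-neuron time scales will be used")
  }

  step <- curve_i0[2] - curve_i0[1]
  cal <- purrr::map_dfr(seq_along(freqs), function(k) {
    f_t <- freqs[k]
    r_t <- f_t * time_scale
    ts_k <- time_scale
    if (r_t < r_lo || r_t > r_hi) {      # per-neuron fallback
      i0_k <- if (r_t > r_hi) i0_hi else i0_lo
      rate <- ml_rate(params, i0_k, dt = dt)
      ts_k <- rate / f_t
    } else {
      i0_est <- approx(curve_r, curve_i0, xout = r_t, rule = 2)$y
      lo <- max(i0_lo, i0_est - 1.5 * step)
      hi <- min(i0_hi, i0_est + 1.5 * step)
      while (ml_rate(params, lo, dt = dt) > r_t && lo > i0_lo)
        lo <- max(i0_lo, lo - step)
      while (ml_rate(params, hi, dt = dt) < r_t && hi < i0_hi)
        hi <- min(i0_hi, hi + step)
      rate <- NA_real_
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        rate <- ml_rate(params, mid, dt = dt)
        if (rate < r_t) lo <- mid else hi <- mid
        if (abs(rate - r_t) / r_t < tol / 5) break
      }
      i0_k <- mid
    }
    tibble(oscillator = k, f_target = f_t, i0 = i0_k, time_scale = ts_k,
           rate = rate, f_realized = rate / ts_k,
           rel_err = abs(rate / ts_k - f_t) / f_t)
  })
  if (any(cal$rel_err > tol))
    abort("bank calibration failed to reach tolerance for some neurons",
          class = "sbf_calibration_error")

  waveforms <- matrix(NA_real_, nrow = bank$n_osc, ncol = n_wave)
  for (k in seq_len(bank$n_osc)) {
    p <- params; p$i0 <- cal$i0[k]
    waveforms[k, ] <- limit_cycle_waveform(p, 1 / cal$rate[k], n_wave, dt)
  }
  # quadrature (Hilbert) companions, for the retained-branch readout
  waveforms_im <- t(apply(waveforms, 1, hilbert_quadrature))

  structure(
    list(bank = bank, params = params, time_scale = time_scale,
         table = cal, waveforms = waveforms, waveforms_im = waveforms_im,
         n_wave = as.integer(n_wave), oscillatory_range = rng),
    class = "ml_bank"
  )
}

# Hilbert transform of one periodic waveform sample (FFT sign-flip method):
# the imaginary part of the analytic signal whose real part is `w`.
hilbert_quadrature <- function(w) {
  n <- length(w)
  W <- stats::fft(w)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- -1i
    h[(n / 2 + 2):n] <- 1i
  } else {
    h[2:((n + 1) / 2)] <- -1i
    h[((n + 1) / 2 + 1):n] <- 1i
  }
  Re(stats::fft(W * h, inverse = TRUE)) / n
}

# One post-transient limit-cycle period of x1, phase-referenced at the x1
# maximum, cycle-mean removed and rescaled to peak amplitude 1. Removing the
# DC component matters: a common non-zero mean across oscillators adds an
# Nc-proportional pedestal to the dot-product output that swamps the
# coincidence peak (the cosine time base is zero-mean by construction).
limit_cycle_waveform <- function(params, period, n_wave, dt) {
  t_end <- max(60, 12 * period) + 2.5 * period
  tr <- integrate_ml(params, t_end, dt)
  tail <- tr[tr$t >= t_end - 2.4 * period, ]
  head_half <- tail[tail$t <= max(tail$t) - 1.1 * period, ]
  t_max <- head_half$t[which.max(head_half$x1)]
  ph_t <- t_max + seq(0, period, length.out = n_wave + 1)[-(n_wave + 1)]
  x <- approx(tail$t, tail$x1, xout = ph_t)$y
  x <- x - mean(x)
  x / max(abs(x))
}

#' @export
print.ml_bank <- function(x, ...) {
  cat(sprintf(
    "<ml_bank> %d calibrated Morris-Lecar neurons (%s) on (%g, %g] Hz\n",
    x$bank$n_osc, x$params$type, x$bank$f1, x$bank$f2))
  cat(sprintf("  time_scale = %.5f s per unit, max |rate error| = %.2e\n",
              x$time_scale, max(x$table$rel_err)))
  invisible(x)
}

#' Oscillator states at given times
#'
#' Generic state read-out used by the SBF engine: the
#' `n_osc x length(times)` matrix of oscillator amplitudes. For a cosine bank
#' this is `cos(2 pi f_k t)`; for a calibrated Morris-Lecar bank it is the
#' stored normalised limit-cycle waveform evaluated at phase
#' `f_k * t mod 1`. Optional frequency multipliers (one per oscillator)
#' implement multiplicative frequency noise.
#'
#' @param bank An [oscillator_bank()] or `ml_bank`.
#' @param times Times in seconds.
#' @param freq_multipliers Optional per-oscillator factors on the base
#'   frequencies.
#' @param quadrature Return the quadrature (Hilbert) companion of each state
#'   instead of the state itself: `sin` for a cosine oscillator, the stored
#'   Hilbert waveform for a Morris-Lecar neuron. Used by the retained-branch
#'   readout of [sbf_output()].
#' @return Numeric matrix, oscillators in rows, times in columns.
#' @export
state_matrix <- function(bank, times, freq_multipliers = NULL,
                         quadrature = FALSE) {
  UseMethod("state_matrix")
}

#' @export
state_matrix.oscillator_bank <- function(bank, times, freq_multipliers = NULL,
                                         quadrature = FALSE) {
  f <- frequency_grid(bank)
  if (!is.null(freq_multipliers)) f <- f * freq_multipliers
  if (quadrature) sin(2 * pi * outer(f, times)) else cosine_state_matrix(f, times)
}

#' @export
state_matrix.ml_bank <- function(bank, times, freq_multipliers = NULL,
                                 quadrature = FALSE) {
  f <- bank$table$f_realized
  if (!is.null(freq_multipliers)) f <- f * freq_multipliers
  ph <- outer(f, times) %% 1
  idx <- pmin(floor(ph * bank$n_wave) + 1L, bank$n_wave)
  wf <- if (quadrature) bank$waveforms_im else bank$waveforms
  vals <- wf[(idx - 1L) * nrow(wf) + seq_len(nrow(idx))]
  dim(vals) <- dim(idx)
  vals
}

n_oscillators <- function(bank) {
  if (inherits(bank, "ml_bank")) bank$bank$n_osc else bank$n_osc
}

base_bank <- function(bank) {
  if (inherits(bank, "ml_bank")) bank$bank else bank
}
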