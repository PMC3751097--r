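#' Define a bank of oscillators on an evenly spaced frequency grid
#'
#' An oscillator bank is the time base of the SBF timing network: `n_osc`
#' oscillators whose base frequencies are equally spaced over `(f1, f2]` with
#' increment `df = (f2 - f1) / n_osc`, so the k-th frequency is
#' `f1 + k * df` for `k = 1, ..., n_osc` and the upper bound `f2` is attained.
#'
#' @param f1 Lower frequency bound in Hz (exclusive); must be positive.
#' @param f2 Upper frequency bound in Hz (attained by the last oscillator).
#' @param n_osc Number of oscillators (positive integer).
#'
#' @return An object of class `oscillator_bank`: a list with elements `f1`,
#'   `f2`, `n_osc` and the derived increment `df`.
#' @examples
#' bank <- oscillator_bank(5.5, 11.5, 600)
#' head(frequency_grid(bank))
#' @export
oscillator_bank <- function(f1, f2, n_osc) {
  if (!is.numeric(f1) || !is.numeric(f2) || length(f1) != 1 || length(f2) != 1)
    abort("`f1` and `f2` must be single numbers", class = "sbf_config_error")
  if (!(f1 > 0))
    abort("`f1` must be positive", class = "sbf_config_error")
  if (!(f2 > f1))
    abort("`f2` must exceed `f1`", class = "sbf_config_error")
  n_osc <- as.integer(n_osc)
  if (is.na(n_osc) || n_osc < 1)
    abort("`n_osc` must be a positive integer", class = "sbf_config_error")
  structure(
    list(f1 = f1, f2 = f2, n_osc = n_osc, df = (f2 - f1) / n_osc),
    class = "oscillator_bank"
  )
}

#' @export
print.oscillator_bank <- function(x, ...) {
  cat(sprintf(
    "<oscillator_bank> %d oscillators on (%g, %g] Hz, df = %g Hz\n",
    x$n_osc, x$f1, x$f2, x$df
  ))
  invisible(x)
}

#' Base frequencies of an oscillator bank
#'
#' @param bank An [oscillator_bank()].
#' @return Numeric vector of `n_osc` strictly increasing frequencies (Hz),
#'   `f1 + k * df` for `k = 1, ..., n_osc`.
#' @export
frequency_grid <- function(bank) {
  stopifnot(inherits(bank, "oscillator_bank"))
  bank$f1 + seq_len(bank$n_osc) * bank$df
}

#' State of a cosine phase oscillator
#'
#' The simplest oscillatory time base: an oscillator of frequency `f` reset to
#' phase zero at `t = 0` has state `cos(2 pi f t)`.
#'
#' @param f Frequency in Hz (positive). Vectorised.
#' @param t Time in seconds. Vectorised (recycled against `f`).
#' @return Amplitude in `[-1, 1]`.
#' @export
cosine_state <- function(f, t) {
  if (any(f <= 0)) abort("frequencies must be positive", class = "sbf_config_error")
  cos(2 * pi * f * t)
}

#' Cosine state matrix for a set of frequencies
#'
#' Returns the `length(freqs) x length(times)` matrix of oscillator states
#' `cos(2 pi f_k t_j)`; the common building block of reference and running
#' weights for cosine banks.
#'
#' @param freqs Frequencies in Hz.
#' @param times Times in seconds.
#' @return Numeric matrix, oscillators in rows, times in columns.
#' @export
cosine_state_matrix <- function(freqs, times) {
  cos(2 * pi * outer(freqs, times))
}
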