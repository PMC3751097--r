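#' Reference (memorised) weight vector at the criterion time
#'
#' The memory block stores, for each oscillator, the sum of its states over
#' the `Nc` noisy retrievals of the criterion time `c * (1 + x)`:
#' `raw_k = sum_i state(k, c_i)`. Weights are the raw sums divided by the
#' normalisation `Norm = max_k raw_k` (signed mode, bounding weights above
#' by 1; if the maximum raw state is non-positive the maximum absolute value
#' is used instead, with a warning). Positive mode maps into `[0, 1]` as
#' `(raw / Norm + 1) / 2` with `Norm = max_k |raw_k|`, which guarantees the
#' unit-interval bound.
#'
#' @param bank An [oscillator_bank()] (cosine states) or `ml_bank`
#'   (normalised membrane-potential states).
#' @param criterion Criterion time in seconds (> 0).
#' @param mem_noise A [noise_spec()] for the stored criterion; `noise_off()`
#'   reproduces the noiseless reference state.
#' @param mode `"signed"` (default) or `"positive"`.
#' @return An `sbf_weights` tibble with columns `oscillator`, `raw`,
#'   `weight`, and attributes `norm`, `criterion`, `mode`, `n_samples`,
#'   `n_resampled`.
#' @examples
#' bank <- oscillator_bank(1, 3, 3)
#' reference_weights(bank, criterion = 1)
#' @export
reference_weights <- function(bank, criterion, mem_noise = noise_off(),
                              mode = c("signed", "positive")) {
  mode <- match.arg(mode)
  criteria <- sample_criteria(criterion, mem_noise)
  raw <- rowSums(state_matrix(bank, as.numeric(criteria)))
  new_sbf_weights(raw, mode,
                  criterion = criterion,
                  n_samples = mem_noise$n_samples,
                  n_resampled = attr(criteria, "n_resampled") %||% 0L)
}

#' Running weight vector at the current time
#'
#' The instantaneous analogue of [reference_weights()]: the oscillator states
#' at running time `t`, normalised the same way. Under frequency noise the
#' raw state is averaged over `n_samples` full draws of perturbed bank
#' frequencies.
#'
#' @param bank An [oscillator_bank()] or `ml_bank`.
#' @param t Current time in seconds.
#' @param freq_noise A [noise_spec()] for the oscillator frequencies.
#' @inheritParams reference_weights
#' @return An `sbf_weights` tibble (attribute `criterion` holds `t`).
#' @export
running_weights <- function(bank, t, freq_noise = noise_off(),
                            mode = c("signed", "positive")) {
  mode <- match.arg(mode)
  n_osc <- n_oscillators(bank)
  if (freq_noise$family == "none") {
    raw <- drop(state_matrix(bank, t))
  } else {
    mult <- matrix(sample_multipliers(freq_noise, freq_noise$n_samples * n_osc),
                   nrow = n_osc)
    raw <- rowMeans(vapply(
      seq_len(freq_noise$n_samples),
      function(j) drop(state_matrix(bank, t, freq_multipliers = mult[, j])),
      numeric(n_osc)
    ))
  }
  new_sbf_weights(raw, mode,
                  criterion = t, n_samples = freq_noise$n_samples,
                  n_resampled = 0L)
}

new_sbf_weights <- function(raw, mode, criterion, n_samples, n_resampled) {
  if (all(raw == 0))
    abort("degenerate normalisation: all raw oscillator states are zero",
          class = "sbf_degenerate_weights")
  if (mode == "positive") {
    norm <- max(abs(raw))
  } else {
    norm <- max(raw)
    if (norm <= 0) {
      warn("maximum raw state is non-positive; normalising by max |raw|")
      norm <- max(abs(raw))
    }
  }
  weight <- switch(mode,
    signed   = raw / norm,
    positive = (raw / norm + 1) / 2
  )
  structure(
    tibble(oscillator = seq_along(raw), raw = raw, weight = weight),
    norm = norm, criterion = criterion, mode = mode,
    n_samples = n_samples, n_resampled = n_resampled,
    class = c("sbf_weights", class(tibble()))
  )
}
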