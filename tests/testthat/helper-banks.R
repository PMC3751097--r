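# Shared fixtures, built in code.

# the standard simulation bank geometries
cosine_bank_small <- function(n = 7) oscillator_bank(5.5, 11.5, n)
cosine_bank_std <- function() oscillator_bank(5.5, 11.5, 1000)

# direct double-sum output for a noiseless cosine bank: the brute-force
# oracle for the closed form
direct_cosine_output <- function(bank, criterion, t_grid) {
  f <- frequency_grid(bank)
  as.numeric(crossprod(cos(2 * pi * outer(f, t_grid)),
                       cos(2 * pi * f * criterion)))
}

# calibrated Morris-Lecar banks are expensive; build each geometry once per
# test run
.ml_cache <- new.env(parent = emptyenv())
test_ml_bank <- function(n = 60) {
  key <- paste0("n", n)
  if (is.null(.ml_cache[[key]]))
    .ml_cache[[key]] <- calibrate_ml_bank(oscillator_bank(5.5, 11.5, n))
  .ml_cache[[key]]
}

# criteria scaled to the bank's beat-recurrence capacity 1/df, mirroring the
# 600-neuron / 30-90 s geometry of the full model
scaled_criteria <- function(bank_or_ml, fracs = c(0.3, 0.45, 0.6)) {
  b <- if (inherits(bank_or_ml, "ml_bank")) bank_or_ml$bank else bank_or_ml
  fracs / b$df
}
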