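#' Describe a fluctuating model parameter
#'
#' Memory noise perturbs the stored criterion time as `c * (1 + x)` and
#' frequency noise perturbs each base frequency as `f * (1 + x)`, where `x`
#' is a zero-mean random variable. `level` is the *relative standard
#' deviation* of `x` for every family, so noise levels are comparable across
#' distributions: the normal family draws `x ~ N(0, level^2)` and the uniform
#' family draws `x ~ U(-level * sqrt(3), +level * sqrt(3))`.
#'
#' @param family One of `"none"`, `"uniform"`, `"normal"`.
#' @param level Relative standard deviation of the multiplier (>= 0). Must be
#'   0 when `family = "none"`.
#' @param n_samples Number of draws: the number of stored criterion samples
#'   (memory noise) or of full bank frequency draws (frequency noise).
#' @param seed Optional integer seed making the draws reproducible.
#'
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("normal", level = 0.01, n_samples = 500, seed = 1)
#' noise_off()
#' @export
noise_spec <- function(family = c("none", "uniform", "normal"),
                       level = 0, n_samples = 1, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) || level < 0)
    abort("`level` must be a single non-negative number",
          class = "sbf_config_error")
  if (family == "none" && level > 0)
    abort('`level` must be 0 when family = "none"', class = "sbf_config_error")
  if (family != "none" && level == 0) family <- "none"
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1)
    abort("`n_samples` must be a positive integer", class = "sbf_config_error")
  structure(
    list(family = family, level = level, n_samples = n_samples, seed = seed),
    class = "noise_spec"
  )
}

#' @rdname noise_spec
#' @export
noise_off <- function() noise_spec("none", 0, 1L)

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> family = %s, level = %g, n_samples = %d%s\n",
              x$family, x$level, x$n_samples,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Draw multiplicative noise samples
#'
#' Draws `n_samples` multipliers `1 + x` according to a [noise_spec()]. With
#' `family = "none"` the multipliers are exactly 1.
#'
#' @param noise A [noise_spec()].
#' @param n Optional override of `noise$n_samples`.
#' @return Numeric vector of multipliers.
#' @export
sample_multipliers <- function(noise, n = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- as.integer(n %||% noise$n_samples)
  draw <- function() {
    switch(noise$family,
      none    = rep(1, n),
      normal  = 1 + rnorm(n, 0, noise$level),
      uniform = 1 + runif(n, -noise$level * sqrt(3), noise$level * sqrt(3))
    )
  }
  if (is.null(noise$seed)) draw() else withr::with_seed(noise$seed, draw())
}

# Sampled criterion times c * (1 + x), resampling any non-positive draws
# (possible at high uniform levels); the resample count is attached as an
# attribute so callers can log it.
sample_criteria <- function(criterion, noise, n = NULL) {
  stopifnot(criterion > 0)
  n <- as.integer(n %||% noise$n_samples)
  draw <- function() {
    out <- criterion * sample_multipliers_raw(noise, n)
    n_resampled <- 0L
    while (any(bad <- out <= 0)) {
      n_resampled <- n_resampled + sum(bad)
      out[bad] <- criterion * sample_multipliers_raw(noise, sum(bad))
    }
    attr(out, "n_resampled") <- n_resampled
    out
  }
  if (is.null(noise$seed)) draw() else withr::with_seed(noise$seed, draw())
}

# as sample_multipliers but never re-seeding (for use inside seeded blocks)
sample_multipliers_raw <- function(noise, n) {
  switch(noise$family,
    none    = rep(1, n),
    normal  = 1 + rnorm(n, 0, noise$level),
    uniform = 1 + runif(n, -noise$level * sqrt(3), noise$level * sqrt(3))
  )
}
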