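#' Dirichlet (sinc-like) envelope of the noiseless output
#'
#' The slowly varying envelope of the noiseless cosine-bank output around the
#' criterion: `sin(pi n df (t - c)) / sin(pi df (t - c))`, which peaks at
#' `t = c` with value `n_osc` (the removable singularity is evaluated
#' exactly).
#'
#' @param bank An [oscillator_bank()].
#' @param criterion Criterion time (s).
#' @param t Times (s); vectorised.
#' @return Envelope values.
#' @export
sinc_envelope <- function(bank, criterion, t) {
  stopifnot(inherits(bank, "oscillator_bank"))
  dirichlet_ratio(t - criterion, bank$n_osc, bank$df)
}

#' Half-maximum width of the noiseless envelope
#'
#' Solves `envelope(c - width / 2) = envelope(c) / 2`, i.e.
#' `sin(pi n df w / 2) / sin(pi df w / 2) = n / 2`, by bracketed
#' root-finding on the first lobe. The result depends only on `n_osc` and
#' `df` (equivalently the frequency range), not on the criterion time: the
#' noiseless model violates the scalar property by construction.
#'
#' @param bank An [oscillator_bank()].
#' @return Full width at half maximum (s).
#' @examples
#' noiseless_width(oscillator_bank(5.5, 11.5, 1000))
#' @export
noiseless_width <- function(bank) {
  stopifnot(inherits(bank, "oscillator_bank"))
  n <- bank$n_osc
  if (n == 1)
    abort("the envelope of a single oscillator is flat; width is undefined",
          class = "sbf_numerical_error")
  u_zero <- 1 / (n * bank$df)            # first zero of the envelope
  f <- function(u) dirichlet_ratio(u, n, bank$df) - n / 2
  root <- tryCatch(
    uniroot(f, lower = u_zero * 1e-9, upper = u_zero * (1 - 1e-9),
            tol = 1e-13),
    error = function(e) abort(
      paste0("half-maximum bracket failed on the first lobe: ",
             conditionMessage(e)),
      class = "sbf_numerical_error")
  )
  2 * root$root
}

#' Local maxima of the envelope
#'
#' The local maxima of the absolute envelope `|sin(n x) / sin(x)|` (with
#' `x = pi df (t - c)`) sit at the roots of `tan(n x0) = n tan(x0)`, solved
#' branch by branch via the equivalent continuous form
#' `n cos(n x0) sin(x0) - sin(n x0) cos(x0) = 0`. The corresponding output
#' values are `y0 = sin(n x0) cos((2 f1 / df + n + 1) x0) / (2 sin(x0))`.
#' The pairs `(x0, y0)` are independent of the criterion time.
#'
#' @param bank An [oscillator_bank()].
#' @param n_branches Number of side-lobe branches to solve.
#' @return A tibble with columns `branch` (0 is the central maximum), `x0`,
#'   `y0`, `t_offset` (`x0 / (pi df)`, seconds from the criterion), and the
#'   residual of the defining equation.
#' @export
envelope_maxima <- function(bank, n_branches = 5) {
  stopifnot(inherits(bank, "oscillator_bank"))
  n <- bank$n_osc
  g <- function(x) n * cos(n * x) * sin(x) - sin(n * x) * cos(x)
  carrier <- 2 * bank$f1 / bank$df + n + 1
  rows <- list(tibble(branch = 0L, x0 = 0, y0 = n / 2, t_offset = 0,
                      residual = 0))
  for (m in seq_len(n_branches)) {
    lo <- m * pi / n + 1e-12
    hi <- (m + 1) * pi / n - 1e-12
    if (hi >= pi / 2) break   # stay on the principal region of sin(x)
    root <- tryCatch(
      uniroot(g, lower = lo, upper = hi, tol = 1e-14),
      error = function(e) abort(
        sprintf("bracketing failed on branch %d: %s", m, conditionMessage(e)),
        class = "sbf_numerical_error")
    )
    x0 <- root$root
    y0 <- 0.5 * sin(n * x0) * cos(carrier * x0) / sin(x0)
    rows[[m + 1]] <- tibble(
      branch = m, x0 = x0, y0 = y0, t_offset = x0 / (pi * bank$df),
      residual = abs(tan(n * x0) - n * tan(x0))
    )
  }
  dplyr::bind_rows(rows)
}

#' Mean-value-theorem width equation
#'
#' Under memory noise the averaged output can be written, via the first mean
#' value theorem for integrals, as a Dirichlet kernel evaluated at a
#' mean-value abscissa `theta` of the noise distribution. The dimensionless
#' half-width `y0` then solves
#' `K(c theta (1 - y0)) = K(c theta) / 2` with
#' `K(u) = sin(pi (f2 - f1) u) cos(pi (f2 + f1) u) / sin(pi df u)`,
#' found here by a dense scan for the first sign change in `y` followed by
#' bracketed root-finding. The returned width obeys
#' `sigma = 2 c theta y0`, proportional to the criterion time by
#' construction: use [predict()] to evaluate the linear law at other
#' criteria.
#'
#' @param bank An [oscillator_bank()].
#' @param criterion Criterion time (s).
#' @param theta Mean-value abscissa (dimensionless, non-zero); see
#'   [theta_mean_abs()] for the default convention.
#' @param n_scan Scan resolution used to bracket the first root.
#' @return An object of class `scalar_width` with fields `theta`, `y0`,
#'   `sigma`, `criterion`, `residual`.
#' @examples
#' bank <- oscillator_bank(5.5, 11.5, 100)
#' sol <- solve_scalar_width(bank, 30, theta = theta_mean_abs(noise_spec("normal", 0.01)))
#' predict(sol, criterion = 60) / predict(sol, criterion = 30)  # exactly 2
#' @export
solve_scalar_width <- function(bank, criterion, theta, n_scan = 20001) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (!is.numeric(theta) || length(theta) != 1 || theta == 0)
    abort("`theta` must be a single non-zero number", class = "sbf_config_error")
  K <- function(u) {
    sin(pi * (bank$f2 - bank$f1) * u) * cos(pi * (bank$f2 + bank$f1) * u) /
      sin(pi * bank$df * u)
  }
  ct <- criterion * theta
  rhs <- K(ct) / 2
  g <- function(y) K(ct * (1 - y)) - rhs
  ys <- seq(1e-9, 1 - 1e-9, length.out = n_scan)
  gs <- g(ys)
  flip <- which(gs[-1] * gs[-length(gs)] <= 0)
  if (length(flip) == 0)
    abort("no solution of the width equation in y0 in (0, 1)",
          class = "sbf_no_solution")
  root <- uniroot(g, lower = ys[flip[1]], upper = ys[flip[1] + 1], tol = 1e-15)
  y0 <- root$root
  structure(
    list(theta = theta, y0 = y0, sigma = 2 * criterion * theta * y0,
         criterion = criterion, residual = abs(g(y0)), bank = bank),
    class = "scalar_width"
  )
}

#' @export
print.scalar_width <- function(x, ...) {
  cat(sprintf(
    "<scalar_width> theta = %g, y0 = %.6g, sigma = %.6g s at c = %g s (residual %.2e)\n",
    x$theta, x$y0, x$sigma, x$criterion, x$residual))
  invisible(x)
}

#' @describeIn solve_scalar_width Width at another criterion via the linear
#'   law `sigma = 2 c theta y0`.
#' @param object A `scalar_width` solution.
#' @param ... Unused.
#' @export
predict.scalar_width <- function(object, criterion = object$criterion, ...) {
  2 * criterion * object$theta * object$y0
}

#' Mean absolute deviation abscissa of a noise distribution
#'
#' The default mean-value abscissa for [solve_scalar_width()]: the mean of
#' `|x|` under the noise distribution, `level * sqrt(2 / pi)` for the normal
#' family and `level * sqrt(3) / 2` for the uniform family.
#'
#' @param noise A [noise_spec()].
#' @return A positive number (zero only for `family = "none"`).
#' @export
theta_mean_abs <- function(noise) {
  stopifnot(inherits(noise, "noise_spec"))
  switch(noise$family,
    none = 0,
    normal = noise$level * sqrt(2 / pi),
    uniform = noise$level * sqrt(3) / 2
  )
}
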