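test_that("the envelope peaks at the criterion with value n_osc", {
  bank <- cosine_bank_small(10)
  expect_equal(sinc_envelope(bank, 30, 30), 10)
  # first zero of the numerator
  expect_equal(sinc_envelope(bank, 30, 30 + 1 / (10 * bank$df)), 0,
               tolerance = 1e-9)
})

test_that("the envelope matches a dense scan of the direct sum scaffold", {
  bank <- cosine_bank_small(9)
  u <- seq(-0.4, 0.4, by = 1e-4)
  direct <- sapply(u, function(ui)
    sum(cos(pi * (2 * seq_len(9) - 10) * bank$df * ui)))
  expect_lt(max(abs(sinc_envelope(bank, 0, u) - direct)), 1e-8)
})

test_that("the noiseless width is criterion-independent and solver-accurate", {
  bank <- oscillator_bank(5.5, 11.5, 10)
  w <- noiseless_width(bank)
  # brute-force scan oracle for the half-max crossing
  u <- seq(1e-6, 1 / (10 * bank$df), by = 1e-7)
  env <- sinc_envelope(bank, 0, u)
  cross <- u[min(which(env <= 10 / 2))]
  expect_equal(w / 2, cross, tolerance = 1e-5)
  # width is defined relative to the criterion, hence identical for any c
  expect_equal(
    uniroot(function(x) sinc_envelope(bank, 30, 30 - x) - 5, c(1e-9, 1.6))$root,
    uniroot(function(x) sinc_envelope(bank, 90, 90 - x) - 5, c(1e-9, 1.6))$root,
    tolerance = 1e-10
  )
})

test_that("doubling the bank at fixed range sharpens the envelope", {
  w1 <- noiseless_width(oscillator_bank(5.5, 11.5, 500))
  w2 <- noiseless_width(oscillator_bank(5.5, 11.5, 1000))
  expect_lt(w2, w1)
})

test_that("envelope maxima satisfy their defining equation", {
  bank <- cosine_bank_small(9)
  mx <- envelope_maxima(bank, n_branches = 3)
  expect_equal(mx$x0[1], 0)
  expect_equal(mx$y0[1], 9 / 2)
  side <- mx[mx$branch > 0, ]
  expect_gt(nrow(side), 0)
  expect_true(all(side$residual < 1e-9))
})

test_that("the first side lobe matches a dense envelope scan", {
  bank <- cosine_bank_small(9)
  mx <- envelope_maxima(bank, n_branches = 1)
  x <- seq(pi / 9 + 1e-9, 2 * pi / 9 - 1e-9, by = 1e-6)
  scan_x0 <- x[which.max(abs(sin(9 * x) / sin(x)))]
  expect_equal(mx$x0[2], scan_x0, tolerance = 1e-6)
})

test_that("the width-equation solution is residual-exact and scales with c", {
  bank <- oscillator_bank(5.5, 11.5, 100)
  theta <- theta_mean_abs(noise_spec("normal", 0.01))
  sol <- solve_scalar_width(bank, 30, theta)
  expect_lt(sol$residual, 1e-10)
  # built-in linearity: sigma/c identical at c and 2c through the linear law
  expect_equal(predict(sol, 60) / 60, predict(sol, 30) / 30,
               tolerance = 1e-12)
  expect_equal(sol$sigma, 2 * 30 * theta * sol$y0, tolerance = 1e-12)
})

test_that("the width-equation root matches a brute-force scan", {
  bank <- oscillator_bank(5.5, 11.5, 100)
  theta <- 0.01
  K <- function(u) sin(pi * 6 * u) * cos(pi * 17 * u) / sin(pi * bank$df * u)
  ct <- 30 * theta
  g <- function(y) K(ct * (1 - y)) - K(ct) / 2
  ys <- seq(1e-9, 1 - 1e-9, length.out = 2e6)
  gs <- g(ys)
  first <- min(which(gs[-1] * gs[-length(gs)] <= 0))
  sol <- solve_scalar_width(bank, 30, theta)
  expect_equal(sol$y0, ys[first], tolerance = 1e-6)
})

test_that("theta defaults follow the mean absolute deviation", {
  expect_equal(theta_mean_abs(noise_spec("normal", 0.1)), 0.1 * sqrt(2 / pi))
  expect_equal(theta_mean_abs(noise_spec("uniform", 0.1)), 0.1 * sqrt(3) / 2)
  expect_equal(theta_mean_abs(noise_off()), 0)
  bank <- oscillator_bank(5.5, 11.5, 100)
  expect_error(solve_scalar_width(bank, 30, 0), class = "sbf_config_error")
})
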