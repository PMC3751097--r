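test_that("vector field matches a term-by-term hand evaluation", {
  p <- ml_params("type2")
  # independent arithmetic oracle at (x1, x2) = (0, 0), bias 0
  minf <- (1 + tanh((0 + 0.01) / 0.15)) / 2
  dx1_hand <- -0.5 * minf * (0 - 1) - 2 * 0 * (0 + 0.7) - 0.5 * (0 + 0.5)
  winf <- (1 + tanh((0 - 0.1) / 0.145)) / 2
  dx2_hand <- (1 / 3) * cosh((0 - 0.1) / (2 * 0.145)) * (winf - 0)
  expect_equal(ml_derivatives(c(0, 0), p), c(dx1_hand, dx2_hand),
               tolerance = 1e-14)
})

test_that("the potassium activation nullcline sits at half activation", {
  p <- ml_params("type1", i0 = 0.1)
  d <- ml_derivatives(c(p$v3, 0.5), p)
  expect_equal(d[2], 0, tolerance = 1e-14)
})

test_that("regime presets carry the published constants", {
  p <- ml_params("type2")
  expect_equal(p$g_ca, 0.5)
  expect_equal(ml_params("type1")$g_ca, 1.0)
  expect_equal(c(p$e_ca, p$e_k, p$e_l), c(1.0, -0.7, -0.5))
  expect_equal(c(p$v1, p$v2, p$v3, p$v4), c(-0.01, 0.15, 0.1, 0.145))
  expect_equal(c(p$g_k, p$g_l, p$xi), c(2.0, 0.5, 1 / 3))
})

test_that("a sub-threshold neuron relaxes to a stable fixed point", {
  p <- ml_params("type2", i0 = 0)
  tr <- integrate_ml(p, t_end = 300, dt = 0.05)
  final <- c(tr$x1[nrow(tr)], tr$x2[nrow(tr)])
  expect_lt(sqrt(sum(ml_derivatives(final, p)^2)), 1e-6)
  # and stays put when restarted there
  tr2 <- integrate_ml(p, t_end = 50, dt = 0.05, init = final)
  expect_lt(max(abs(tr2$x1 - final[1])), 1e-6)
})

test_that("integration converges at fourth order under step halving", {
  p <- ml_params("type2", i0 = 0.22)   # oscillatory run
  at_end <- function(dt) {
    tr <- integrate_ml(p, t_end = 20, dt = dt)
    c(tr$x1[nrow(tr)], tr$x2[nrow(tr)])
  }
  e1 <- sqrt(sum((at_end(0.1) - at_end(0.05))^2))
  e2 <- sqrt(sum((at_end(0.05) - at_end(0.025))^2))
  expect_gt(e1 / e2, 11)
  expect_lt(e1 / e2, 22)
})

test_that("x2 stays within the activation range on oscillatory runs", {
  tr <- integrate_ml(ml_params("type2", i0 = 0.22), t_end = 200, dt = 0.05)
  expect_true(all(tr$x2 >= -1e-6 & tr$x2 <= 1 + 1e-6))
})

test_that("period measurement recovers a known sinusoid", {
  t <- seq(0, 10, by = 0.001)
  trace <- tibble::tibble(t = t, x1 = cos(2 * pi * 2 * t))
  p <- measure_period(trace)
  expect_equal(p$period, 0.5, tolerance = 1e-6)
  expect_lt(p$cv, 1e-6)
})

test_that("constant traces raise a not-oscillating error", {
  trace <- tibble::tibble(t = seq(0, 10, 0.01), x1 = rep(0.3, 1001))
  expect_error(measure_period(trace), class = "sbf_not_oscillating")
})

test_that("mean-crossing period agrees with a peak-to-peak oracle", {
  tr <- integrate_ml(ml_params("type2", i0 = 0.22), t_end = 600, dt = 0.01)
  period <- measure_period(tr)$period
  # independent oracle: spacing of local maxima after the transient
  keep <- tr$t > 200
  x <- tr$x1[keep]; t <- tr$t[keep]
  i <- 2:(length(x) - 1)
  pk <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  pk <- pk[x[pk] > mean(x)]           # ignore any sub-threshold ripples
  oracle <- mean(diff(t[pk]))
  expect_equal(period, oracle, tolerance = 1e-3)
})

test_that("frequency calibration is self-consistent and hits its target", {
  p <- ml_params("type2")
  mid_rate <- sbftiming:::ml_rate(p, 0.22)
  cal <- calibrate_frequency(p, target_f = mid_rate / 0.012,
                             search_range = c(0.16, 0.28),
                             time_scale = 0.012)
  expect_lt(cal$rel_err, 0.005)
  expect_false(cal$rescaled)
  # unattainable target triggers the time-scale fallback
  cal2 <- calibrate_frequency(p, target_f = 100,
                              search_range = c(0.16, 0.28),
                              time_scale = 0.012)
  expect_true(cal2$rescaled)
  expect_lt(cal2$rel_err, 0.005)
})

test_that("a grid with no oscillation raises an empty-range error", {
  expect_error(find_oscillatory_range(ml_params("type2"), c(0, 0.01)),
               class = "sbf_empty_range")
})

test_that("calibrated banks realise their Hz targets within tolerance", {
  mlb <- test_ml_bank(60)
  expect_true(all(mlb$table$rel_err <= 0.005))
  expect_equal(mlb$table$f_target, frequency_grid(mlb$bank))
  # all oscillators start in phase at t = 0 (reset convention)
  s0 <- drop(state_matrix(mlb, 0))
  expect_true(all(s0 > 0.99))
  # states are periodic with the realised period
  k <- 30
  expect_equal(state_matrix(mlb, 1 / mlb$table$f_realized[k])[k, 1],
               state_matrix(mlb, 0)[k, 1])
})

test_that("model parameters survive a YAML round trip", {
  p <- ml_params("type1", i0 = 0.17, g_ca = 1.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ml_params(p, path)
  expect_equal(read_ml_params(path), p)
})
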