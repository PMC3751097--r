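test_that("an exactly Gaussian input is recovered to machine precision", {
  t <- seq(25, 35, by = 0.01)
  tr <- tibble::tibble(t = t, value = 3.7 * exp(-(t - 30.2)^2 / (2 * 0.8^2)))
  fit <- fit_gaussian(tr)
  expect_equal(fit$amplitude, 3.7, tolerance = 1e-8)
  expect_equal(fit$center, 30.2, tolerance = 1e-8)
  expect_equal(fit$sigma, 0.8, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("monotone data cannot silently pass as a Gaussian peak", {
  t <- seq(0, 10, by = 0.01)
  tr <- tibble::tibble(t = t, value = 0.1 * t)
  res <- tryCatch(fit_gaussian(tr), error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "sbf_fit_error")
  } else {
    expect_lt(res$r2, 0.5)
  }
})

test_that("too little data raises an insufficient-data error", {
  tr <- tibble::tibble(t = 1:3, value = c(1, 2, 1))
  expect_error(fit_gaussian(tr), class = "sbf_insufficient_data")
})

test_that("oscillatory traces are fitted through their maxima hull", {
  t <- seq(25, 35, by = 0.005)
  env <- exp(-(t - 30)^2 / (2 * 1.1^2))
  tr <- tibble::tibble(t = t, value = env * cos(2 * pi * 17 * t))
  fit <- fit_gaussian(tr)
  expect_equal(fit$center, 30, tolerance = 0.02)
  expect_equal(fit$sigma, 1.1, tolerance = 0.02)
  expect_gt(fit$r2, 0.99)
})

test_that("noisy cosine-bank outputs yield high-quality Gaussian envelopes", {
  bank <- cosine_bank_std()
  ns <- noise_spec("normal", 0.01, 500, seed = 21)
  tr <- memory_noise_output(bank, 30, mem_noise = ns, keep_batches = 50)
  env <- burst_envelope(tr)
  fit <- fit_gaussian(env, window = c(30 - 1.3, 30 + 1.3))
  expect_gt(fit$r2, 0.95)
  expect_lt(abs(fit$center - 30), 0.05)
  expect_equal(fit$sigma, sqrt(2) * 0.3, tolerance = 0.25)
})

test_that("halfmax width measured from traces matches the solver", {
  bank <- cosine_bank_std()
  tr <- memory_noise_output(bank, 60)
  expect_equal(trace_halfmax_width(tr), noiseless_width(bank),
               tolerance = 0.05)   # hull sampled once per carrier cycle
})

test_that("proportional widths regress to slope with unit r-squared", {
  pts <- tibble::tibble(criterion = c(30, 60, 90), sigma = 0.012 * c(30, 60, 90))
  reg <- suppressWarnings(width_vs_criterion(pts))  # perfect fit
  expect_equal(reg$slope, 0.012, tolerance = 1e-12)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_equal(reg$r2, 1)
  expect_error(width_vs_criterion(pts[1:2, ]), class = "sbf_config_error")
})

test_that("regressions accept lists of fits and expose tidiers", {
  t <- seq(-5, 5, by = 0.01)
  fits <- lapply(c(0.5, 1, 1.5), function(s) {
    fit_gaussian(tibble::tibble(t = t, value = exp(-t^2 / (2 * s^2))))
  })
  reg <- width_vs_criterion(fits, criteria = c(30, 60, 90))
  expect_equal(reg$slope, 1 / 60, tolerance = 1e-6)
  td <- tidy(reg)
  expect_equal(td$estimate[td$term == "slope"], reg$slope)
  gl <- glance(reg)
  expect_named(gl, c("slope", "slope_se", "intercept", "r2", "n"))
  expect_equal(glance(fits[[2]])$sigma, 1, tolerance = 1e-8)
})

test_that("identical traces superimpose exactly", {
  bank <- cosine_bank_small(40)
  tr <- memory_noise_output(bank, 30)
  sp <- superpose(list(tr, tr))
  expect_equal(sp$max_rms, 0)
})

test_that("scalar-compliant outputs superimpose, constant-width ones do not", {
  bank <- cosine_bank_std()
  ns <- function(seed) noise_spec("normal", 0.05, 300, seed = seed)
  noisy <- lapply(c(30, 90), function(cc) {
    tr <- memory_noise_output(bank, cc, mem_noise = ns(cc), keep_batches = 30)
    env <- burst_envelope(tr)
    attr(env, "config") <- list(criterion = cc)
    env
  })
  noiseless <- lapply(c(30, 90), function(cc) {
    tr <- memory_noise_output(bank, cc)
    env <- tibble::tibble(t = tr$t, value = abs(sinc_envelope(bank, cc, tr$t)))
    attr(env, "config") <- list(criterion = cc)
    env
  })
  rms_noisy <- superpose(noisy)$max_rms
  rms_const <- superpose(noiseless)$max_rms
  expect_lt(rms_noisy, 0.12)
  expect_gt(rms_const, 2 * rms_noisy)
})

test_that("non-overlapping relative supports raise an alignment error", {
  a <- tibble::tibble(t = seq(29, 31, 0.01), value = rnorm(201))
  b <- tibble::tibble(t = seq(89, 91, 0.01), value = rnorm(201))
  attr(a, "config") <- list(criterion = 30)
  attr(b, "config") <- list(criterion = 900)
  expect_error(superpose(list(a, b)), class = "sbf_alignment_error")
})
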