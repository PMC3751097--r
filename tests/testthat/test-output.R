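test_that("closed form equals the direct double sum on random banks", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    f1 <- runif(1, 0.5, 10)
    bank <- oscillator_bank(f1, f1 + runif(1, 0.5, 10), n)
    cc <- runif(1, 1, 40)
    tg <- seq(cc - 2, cc + 2, length.out = 701)
    expect_lt(
      max(abs(closed_form_output(bank, cc, tg)$value -
                direct_cosine_output(bank, cc, tg))),
      1e-8
    )
  }
})

test_that("the closed form handles its removable singularities", {
  bank <- cosine_bank_small(10)
  # t - c and t + c hitting multiples of 1/df exactly
  tg <- c(30, 30 + 1 / bank$df, 1 / bank$df - 30)
  v <- closed_form_output(bank, 30, tg)$value
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(v - direct_cosine_output(bank, 30, tg))), 1e-8)
})

test_that("the dot-product output matches the direct sum and peaks at c", {
  bank <- cosine_bank_small(7)
  tg <- seq(28, 32, by = 0.002)
  out <- sbf_output(bank, 30, tg)
  expect_lt(max(abs(out$value - direct_cosine_output(bank, 30, tg))), 1e-8)
})

test_that("a single-oscillator output is the plain cosine product", {
  bank <- oscillator_bank(1, 2, 1)    # one 2 Hz oscillator
  tg <- seq(0, 3, by = 0.01)
  out <- sbf_output(bank, 2, tg)      # f * c integer: peak magnitude at t = c
  expect_equal(out$value, cos(2 * pi * 2 * 2) * cos(2 * pi * 2 * tg),
               tolerance = 1e-12)
  expect_equal(abs(out$value[which(tg == 2)]), max(abs(out$value)),
               tolerance = 1e-12)
})

test_that("output at the reset instant equals the summed reference weights", {
  bank <- cosine_bank_small(21)
  w <- reference_weights(bank, criterion = 9)
  out <- suppressWarnings(sbf_output(bank, 9, t_grid = c(0, 9)))  # 2-point grid
  expect_equal(out$value[1], sum(w$raw), tolerance = 1e-9)
})

test_that("enumerated criterion samples match a hand-built kernel sum", {
  bank <- cosine_bank_small(5)
  f <- frequency_grid(bank)
  samples <- c(29.7, 30.1, 30.25)
  tg <- seq(29, 31, by = 0.01)
  out <- memory_noise_output(bank, 30, tg, criteria = samples)
  hand <- rowSums(sapply(samples, function(cj)
    0.5 * colSums(cos(2 * pi * outer(f, tg - cj)))))
  expect_lt(max(abs(out$value - hand)), 1e-10)
})

test_that("a degenerate single sample reduces to the noiseless branch", {
  bank <- cosine_bank_small(9)
  tg <- seq(29, 31, by = 0.005)
  a <- memory_noise_output(bank, 30, tg, criteria = 30)
  b <- memory_noise_output(bank, 30, tg)   # family none, one sample at c
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("normal and uniform memory noise both centre the burst on c", {
  bank <- cosine_bank_std()
  for (fam in c("normal", "uniform")) {
    ns <- noise_spec(fam, 0.01, 300, seed = 8)
    out <- memory_noise_output(bank, 30, mem_noise = ns, keep_batches = 30)
    env <- burst_envelope(out)
    pk <- env$t[which.max(env$value)]
    expect_lt(abs(pk - 30), 0.01 * 30)   # within the noise spread of c
  }
})

test_that("the retained-branch projection equals the closed-form branch", {
  bank <- cosine_bank_small(50)
  ns <- noise_spec("normal", 0.01, 40, seed = 5)
  tg <- seq(19, 21, by = 0.004)
  a <- sbf_output(bank, 20, tg, mem_noise = ns, branch = "retained")
  b <- memory_noise_output(bank, 20, tg, mem_noise = ns)
  expect_lt(max(abs(a$value - b$value)), 1e-8)
})

test_that("cosine-angle similarity is bounded and maximal at coincidence", {
  bank <- cosine_bank_small(25)
  tg <- seq(9, 11, by = 0.004)
  out <- sbf_output(bank, 10, tg, similarity = "cosine_angle")
  expect_true(all(out$value >= 0 & out$value <= 1 + 1e-12))
  expect_equal(out$value[which(abs(tg - 10) < 1e-9)], 1, tolerance = 1e-9)
})

test_that("outputs converge to the noiseless limit as noise vanishes", {
  bank <- cosine_bank_small(30)
  tg <- seq(14, 16, by = 0.004)
  ref <- sbf_output(bank, 15, tg)$value
  # raw dot products scale with the number of stored samples; compare means
  dev <- sapply(c(1e-3, 1e-4, 1e-5), function(lvl) {
    max(abs(sbf_output(bank, 15, tg,
                       mem_noise = noise_spec("normal", lvl, 50, seed = 6)
    )$value / 50 - ref))
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-2)
})

test_that("identical seeds reproduce outputs bit for bit", {
  bank <- cosine_bank_small(40)
  ns <- noise_spec("uniform", 0.02, 100, seed = 123)
  fs <- noise_spec("normal", 0.005, 7, seed = 321)
  a <- sbf_output(bank, 12, mem_noise = ns, freq_noise = fs)
  b <- sbf_output(bank, 12, mem_noise = ns, freq_noise = fs)
  expect_identical(a$value, b$value)
})

test_that("frequency-noise averaging uses independent bank draws", {
  bank <- cosine_bank_small(20)
  tg <- seq(9.5, 10.5, by = 0.004)
  out <- sbf_output(bank, 10, tg,
                    freq_noise = noise_spec("normal", 0.002, 20, seed = 2))
  ref <- sbf_output(bank, 10, tg)
  # averaged output stays close to noiseless and keeps the peak at c
  expect_lt(mean(abs(out$value - ref$value)) / max(ref$value), 0.2)
  expect_equal(tg[which.max(out$value)], 10, tolerance = 0.01)
})
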