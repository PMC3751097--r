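test_that("experiment configurations survive a YAML round trip", {
  cfg <- experiment_config(
    name = "roundtrip", kind = "cosine", f1 = 4, f2 = 9, n_osc = 123,
    criteria = c(10, 20), mem_noise = noise_spec("uniform", 0.02, 250),
    seed = 99
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$bank, cfg$bank)
  expect_equal(back$criteria, cfg$criteria)
  expect_equal(back$mem_noise$family, "uniform")
  expect_equal(back$mem_noise$level, 0.02)
  expect_equal(back$seed, 99L)
})

test_that("experiment runners enforce their preconditions", {
  noisy <- experiment_config(mem_noise = noise_spec("normal", 0.1, 10))
  expect_error(run_noiseless_sbf(noisy), class = "sbf_usage_error")
  expect_error(run_memory_noise_sbf(experiment_config()),
               class = "sbf_usage_error")
  expect_error(run_ml_sbf(experiment_config(kind = "cosine")),
               class = "sbf_usage_error")
})

test_that("noiseless runs give constant widths and criterion-located peaks", {
  cfg <- experiment_config(criteria = c(30, 60, 90))
  ex <- run_noiseless_sbf(cfg)
  expect_equal(max(ex$widths$width_halfmax) / min(ex$widths$width_halfmax), 1,
               tolerance = 0.01)
  expect_equal(ex$widths$peak, rep(500, 3), tolerance = 0.01)
  peaks <- ex$traces |>
    dplyr::group_by(criterion) |>
    dplyr::summarise(at = t[which.max(value)])
  expect_equal(peaks$at, peaks$criterion, tolerance = 1e-6)
})

test_that("memory-noise runs are reproducible under their seed", {
  cfg <- experiment_config(n_osc = 300, criteria = c(10, 20, 30),
                           mem_noise = noise_spec("normal", 0.02, 200),
                           seed = 7)
  a <- run_memory_noise_sbf(cfg)
  b <- run_memory_noise_sbf(cfg)
  expect_identical(a$widths$sigma, b$widths$sigma)
  expect_gt(a$regression$slope, 0)
})

test_that("scaled-down biophysical banks reproduce the slope pattern", {
  mlb <- test_ml_bank(60)        # capacity 1/df = 10 s
  cfg <- experiment_config(kind = "ml", n_osc = 60L,
                           criteria = scaled_criteria(mlb),
                           mem_noise = noise_spec("normal", 0.01, 300),
                           seed = 3)
  ex <- run_ml_sbf(cfg, levels = c(0.01, 0.1), ml_bank = mlb)
  expect_true(all(diff(ex$summary$slope) > 0))
  ratio <- ex$summary$slope[2] / ex$summary$slope[1]
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})
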