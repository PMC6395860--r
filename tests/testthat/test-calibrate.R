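test_that("the update rule moves drives along the signed rate error", {
  tg <- calibration_target()
  expect_gt(ctcstim:::cal_step(1000, 5, tg), 1000)     # rate too low: increase
  expect_lt(ctcstim:::cal_step(1000, -5, tg), 1000)    # rate too high: decrease
  # the relative step is capped regardless of the error magnitude
  expect_equal(ctcstim:::cal_step(1000, 1e6, tg), 1200)
  expect_equal(ctcstim:::cal_step(1000, -1e6, tg), 800)
})

test_that("a calibrated configuration is a fixed point of the loop", {
  cal <- calibrate_drives(col_config(), seed = 11)
  expect_true(cal$converged)
  expect_equal(cal$iterations, 1)
  expect_lt(abs(cal$achieved[["rate_exc"]] - 15), 1)
  expect_lt(abs(cal$achieved[["rate_inh"]] - 60), 3)
})

test_that("a zero learning rate leaves the drives untouched and is flagged", {
  tg <- calibration_target(rate_exc = 5, rate_inh = 20, learning_rate = 0,
                           max_iter = 2, probe_duration = 2)
  cfg <- build_single_column(noise_level = 0.075e-9, seed = 2)
  cal <- calibrate_drives(cfg, tg, seed = 11)
  expect_false(cal$converged)
  expect_equal(cal$rates[["rate_exc"]], cfg$drives$col$rate_exc)
  expect_equal(cal$rates[["rate_inh"]], cfg$drives$col$rate_inh)
})

test_that("calibration targets validate their preconditions", {
  expect_error(calibration_target(tol_exc = 0))
  expect_error(calibration_target(probe_duration = 1))
  expect_error(calibrate_drives(build_single_column(
    noise_level = 0, seed = 1,
    drive_rates = c(rate_exc = 0, rate_inh = 0))), "no driven")
})
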