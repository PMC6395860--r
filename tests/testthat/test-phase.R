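fs <- 1000

test_that("gamma-band estimation finds single tones and rejects flat spectra", {
  t <- (0:4999) / fs
  x <- cos(2 * pi * 65 * t) + with_local_seed(1, rnorm(5000, 0, 0.1))
  b <- estimate_gamma_band(analog_trace(x, fs))
  expect_lt(abs(b$f_peak - 65), 1)
  expect_lt(b$f_lo, 65)
  expect_gt(b$f_hi, 65)
  # two tones, the lower slightly stronger: smoothing keeps the stronger one
  x2 <- cos(2 * pi * 40 * t) + 0.9 * cos(2 * pi * 80 * t)
  expect_equal(estimate_gamma_band(analog_trace(x2, fs))$f_peak, 40,
               tolerance = 0.05)
  expect_error(estimate_gamma_band(analog_trace(x[1:500], fs)), "1 s")
})

test_that("offline phase reproduces analytic phases of sinusoids", {
  t <- (0:4999) / fs
  band <- bandpass_spec(65, 50, 80)
  pc <- offline_phase(analog_trace(cos(2 * pi * 65 * t), fs), band)
  expected <- wrap_angle(2 * pi * 65 * t)
  err <- wrap_angle(pc$phase - expected)[pc$valid]
  expect_lt(max(abs(err)), 0.05)
  ps <- offline_phase(analog_trace(sin(2 * pi * 65 * t), fs), band)
  ok <- pc$valid & ps$valid
  d <- wrap_angle(ps$phase - pc$phase)[ok]
  expect_lt(max(abs(d + pi / 2)), 0.05)       # quadrature identity
})

test_that("offline phase is invariant to positive rescaling and mean shifts", {
  t <- (0:2999) / fs
  x <- cos(2 * pi * 60 * t) + with_local_seed(2, rnorm(3000, 0, 0.2))
  band <- bandpass_spec(60, 45, 78)
  p1 <- offline_phase(analog_trace(x, fs), band)
  p2 <- offline_phase(analog_trace(5 * x + 3, fs), band)
  expect_equal(p1$phase, p2$phase, tolerance = 1e-9)
})

test_that("artifact windows are zeroed and guarded", {
  t <- (0:2999) / fs
  x <- cos(2 * pi * 60 * t)
  band <- bandpass_spec(60, 45, 78)
  p <- offline_phase(analog_trace(x, fs), band,
                     artifact_windows = list(c(1.0, 1.02)))
  i <- round(c(0.985, 1.01, 1.045) * fs)
  expect_false(any(p$valid[i[1]:i[3]]))       # 30 ms guard on both sides
  expect_true(p$valid[round(0.9 * fs)])
  expect_true(p$valid[round(1.1 * fs)])
})

test_that("Burg fitting recovers AR structure", {
  z <- with_local_seed(3, as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)),
                                                      1e5)))
  m <- fit_ar(analog_trace(z, fs), order = 2)
  expect_lt(max(abs(m$coeffs - c(0.5, -0.3))), 0.02)
  # a pure sinusoid is AR-representable: tiny one-step prediction error
  t <- (0:9999) / fs
  s <- sin(2 * pi * 60 * t)
  ms <- fit_ar(analog_trace(s, fs), order = 15)
  expect_lt(ms$noise_std, 1e-3)
  # white noise carries no linear structure
  w <- with_local_seed(4, rnorm(1e5))
  mw <- fit_ar(analog_trace(w, fs), order = 10)
  expect_lt(max(abs(mw$coeffs)), 0.05)
  expect_error(fit_ar(analog_trace(w[1:5], fs), order = 10), "order")
})

test_that("real-time phase matches the offline phase on a noiseless tone", {
  t <- (0:2999) / fs
  x <- cos(2 * pi * 63 * t)
  band <- bandpass_spec(63, 48, 78)
  m <- fit_ar(analog_trace(x, fs), order = 15, band = band)
  for (i in c(800, 1500, 2200)) {
    rt <- realtime_phase(m, analog_trace(x[1:i], fs), band)
    expect_lt(abs(wrap_angle(rt - wrap_angle(2 * pi * 63 * t[i]))), 0.02)
  }
  expect_error(realtime_phase(m, analog_trace(x[1:10], fs), band), "history")
  expect_error(realtime_phase(m, analog_trace(x[1:500], fs), band,
                              horizon = 0.01), "horizon")
})

test_that("real-time phase tracks offline phase on network activity", {
  band <- col_band()
  ar <- col_ar()
  sig <- analysis_signal(col_run(), "col")
  off <- offline_phase(sig, band)
  ts <- seq(1, 9.5, length.out = 30)
  d <- vapply(ts, function(tp) {
    i <- round(tp * 1000)
    rt <- realtime_phase(ar, analog_trace(sig$samples[1:i], fs), band)
    wrap_angle(rt - off$phase[i])
  }, numeric(1))
  cs <- circular_stats(d)
  expect_lt(abs(cs$mean), 0.3)                       # distribution mode at 0
  expect_lt(sqrt(-2 * log(cs$resultant)), 0.6)       # circular sd bound
})

test_that("circular statistics handle symmetry, wraparound and degeneracy", {
  s <- circular_stats(c(0.1, -0.1))
  expect_equal(s$mean, 0)
  expect_equal(s$resultant, cos(0.1), tolerance = 1e-9)
  s2 <- circular_stats(c(pi - 0.1, -pi + 0.1))
  expect_lt(circ_dist(s2$mean, pi), 1e-9)            # wraps through pi
  # explicit vector sum oracle: four orthogonal unit vectors cancel
  s3 <- circular_stats(c(0, pi / 2, pi, 3 * pi / 2))
  expect_true(s3$undefined)
  expect_error(circular_stats(numeric(0)), "empty")
})
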