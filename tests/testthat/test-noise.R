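test_that("pink noise has unit sample sd and zero mean at any length", {
  for (n in c(500, 5000, 2^16)) {
    x <- generate_pink_noise(n, seed = n)
    expect_lt(abs(sd(x) - 1), 0.02)
    expect_lt(abs(mean(x)), 1e-12)
  }
  expect_error(generate_pink_noise(1), "n_samples")
})

test_that("pink noise spectral density falls as 1/f over the resolvable band", {
  x <- generate_pink_noise(2^17, dt = 1e-4, seed = 3)
  sp <- stats::spec.pgram(stats::ts(as.numeric(x), frequency = 1e4),
                          taper = 0, plot = FALSE, spans = 31)
  sel <- sp$freq >= 1 & sp$freq <= 500
  slope <- stats::coef(stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2]
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
})

test_that("pink noise is reproducible by seed and distinct across seeds", {
  expect_identical(as.numeric(generate_pink_noise(1000, seed = 5)),
                   as.numeric(generate_pink_noise(1000, seed = 5)))
  expect_false(identical(as.numeric(generate_pink_noise(1000, seed = 5)),
                         as.numeric(generate_pink_noise(1000, seed = 6))))
})

test_that("flicker holds one uniform value per window", {
  f <- generate_flicker(0.1, step = 0.01, seed = 2)
  expect_length(f$values, 10)
  expect_length(unique(f$values), 10)
  tr <- flicker_trace(f, fs = 1000)
  expect_length(tr, 100)
  expect_equal(unique(tr[1:10]), f$values[1])
  expect_equal(tr[11], f$values[2])
  expect_error(generate_flicker(0.005, step = 0.01), "duration")
})

test_that("flicker draws have the Uniform[-1,1] moments", {
  f <- generate_flicker(1e4, step = 0.01, seed = 9)   # one million draws
  expect_lt(abs(mean(f$values)), 0.01)
  # oracle: Var of Uniform(-1, 1) is (1 - (-1))^2 / 12 = 1/3
  expect_lt(abs(var(f$values) - 1 / 3), 0.01)
  expect_true(all(f$values >= -1 & f$values <= 1))
})
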