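fs <- 1000

test_that("Morlet spectrogram has flat amplitude on tones and kills DC", {
  t <- (0:9999) / fs
  st <- morlet_spectrogram(analog_trace(sin(2 * pi * 30 * t), fs),
                           c(10, 30, 44))
  amp <- Mod(st$coeffs[2, 2000:8000])
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.01)
  dc <- morlet_spectrogram(analog_trace(rep(2, 4000), fs), seq(4, 44, 4))
  expect_lt(max(Mod(dc$coeffs)), 1e-10)
  expect_error(morlet_spectrogram(analog_trace(t, fs), numeric(0)), "empty")
  expect_error(morlet_spectrogram(analog_trace(t, fs), c(30, 10)), "increasing")
})

test_that("the spectrogram ridge tracks a chirp's instantaneous frequency", {
  t <- (0:9999) / fs
  f0 <- 20; f1 <- 40
  x <- sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * 10)))   # 20 -> 40 Hz
  st <- morlet_spectrogram(analog_trace(x, fs), seq(10, 50, 1))
  for (tp in c(2, 5, 8)) {
    ridge <- st$freqs[which.max(Mod(st$coeffs[, tp * 1000]))]
    f_inst <- f0 + (f1 - f0) * tp / 10
    expect_lt(abs(ridge - f_inst), 2)
  }
})

test_that("self-coherence is one at zero lag and a pure delay moves the peak", {
  x <- with_local_seed(5, as.numeric(stats::filter(rnorm(8000), rep(0.25, 4),
                                                   sides = 2)))
  x[is.na(x)] <- 0
  freqs <- seq(4, 45, 1)
  sx <- morlet_spectrogram(analog_trace(x, fs), freqs)
  m <- spectral_coherence(sx, sx, lags = seq(-0.05, 0.05, 1e-3))
  expect_true(all(abs(m$values[, m$lags == 0] - 1) < 1e-9))
  d <- 15
  y <- c(numeric(d), x[1:(8000 - d)])
  sy <- morlet_spectrogram(analog_trace(y, fs), freqs)
  m2 <- spectral_coherence(sx, sy, lags = seq(-0.05, 0.05, 1e-3))
  peak_lags <- m2$lags[apply(m2$values, 1, which.max)]
  expect_true(all(abs(peak_lags[freqs >= 10] - d / fs) < 2e-3))
})

test_that("independent signals stay near the sampling floor of the estimator", {
  freqs <- seq(20, 45, 1)
  x <- with_local_seed(6, rnorm(10000))
  y <- with_local_seed(7, rnorm(10000))
  m <- spectral_coherence(morlet_spectrogram(analog_trace(x, fs), freqs),
                          morlet_spectrogram(analog_trace(y, fs), freqs),
                          lags = seq(-0.05, 0.05, 1e-3))
  # Monte-Carlo oracle: null coherence scale for this duration and band
  null_max <- vapply(1:5, function(k) {
    a <- with_local_seed(100 + k, rnorm(10000))
    b <- with_local_seed(200 + k, rnorm(10000))
    max(spectral_coherence(morlet_spectrogram(analog_trace(a, fs), freqs),
                           morlet_spectrogram(analog_trace(b, fs), freqs),
                           lags = c(-0.02, 0, 0.02))$values)
  }, numeric(1))
  expect_lt(max(m$values), 3 * max(null_max))
  expect_lt(max(m$values), 0.35)
})

test_that("printed-denominator variant keeps self-coherence below one", {
  x <- with_local_seed(8, rnorm(6000))
  sx <- morlet_spectrogram(analog_trace(x, fs), seq(10, 40, 2))
  m <- spectral_coherence(sx, sx, lags = 0, normalization = "printed")
  expect_true(all(m$values < 1))
  expect_true(all(m$values > 0))
})

test_that("cone pooling averages exactly the in-cone cells", {
  freqs <- seq(4, 45, 1)
  lags <- seq(-0.35, 0.35, 1e-3)
  mk <- function(v) structure(list(values = matrix(v, length(freqs),
                                                   length(lags)),
                                   freqs = freqs, lags = lags,
                                   n_times = 1000), class = "ctc_coherence")
  expect_equal(as.numeric(pool_sc(mk(1), cone_of_interest(tau_center = 0))), 1)
  expect_equal(as.numeric(pool_sc(mk(0), cone_of_interest(tau_center = 0))), 0)
  # the half-width 7/(6 f) shrinks with f: higher rows contribute fewer lags
  m <- mk(0)
  m$values[freqs == 10, abs(lags) <= 7 / 60] <- 1
  sc10 <- as.numeric(pool_sc(m, cone_of_interest(tau_center = 0)))
  expect_gt(sc10, 0)
  expect_error(pool_sc(mk(1), cone_of_interest(f_min = 100, f_max = 120)),
               "empty cone")
})

test_that("chance level separates true pairings from surrogates", {
  dur <- 8
  fl <- generate_flicker(dur, seed = 40)
  noise <- with_local_seed(41, rnorm(dur * fs, 0, 0.8))
  out <- analog_trace(flicker_trace(fl, fs) + noise, fs)
  true_sc <- sc_score(out, fl)
  ch <- chance_level(out, function(i) generate_flicker(dur, seed = 500 + i),
                     n_surrogates = 100)
  expect_gt(true_sc, ch)
  scores <- attr(ch, "scores")
  expect_length(scores, 100)
  expect_lte(stats::quantile(scores, 0.5), stats::quantile(scores, 0.95))
  # an output unrelated to any flicker mostly stays below the 95th percentile
  indep <- analog_trace(with_local_seed(42, rnorm(dur * fs)), fs)
  ch2 <- chance_level(indep, function(i) generate_flicker(dur, seed = 700 + i),
                      n_surrogates = 100)
  sc_indep <- sc_score(indep, generate_flicker(dur, seed = 999))
  expect_lt(sc_indep, as.numeric(ch2) * 1.2)
})

test_that("coherence refuses unequal durations (sample-size bias)", {
  x <- rnorm(4000)
  sx <- morlet_spectrogram(analog_trace(x, fs), seq(10, 40, 2))
  sy <- morlet_spectrogram(analog_trace(x[1:3000], fs), seq(10, 40, 2))
  expect_error(spectral_coherence(sx, sy), "equal duration")
  expect_error(sc_score(analog_trace(x, fs), x[1:3000]), "equal duration")
})
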