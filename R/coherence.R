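# Wavelet spectral coherence between the input flicker modulation and
# population output, pooled over a cone of interest into a single
# signal-content score SC-bar, with surrogate-based chance levels.

#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with Morlet kernels (center-frequency
#' parameter 6 cycles), computed by FFT convolution. Coefficients encode
#' amplitude and phase of the signal around each frequency; the amplitude
#' response to a unit sinusoid is flat over interior times.
#'
#' @param trace \code{\link{analog_trace}} or numeric vector (1 kHz).
#' @param freqs strictly increasing frequency grid (Hz), within (0, fs/2).
#' @param w0 Morlet center-frequency parameter (cycles).
#' @return \code{ctc_spectrogram}: list(coeffs [nfreq x ntime complex],
#'   freqs, times, fs).
#' @export
morlet_spectrogram <- function(trace, freqs, w0 = 6) {
  trace <- as_trace(trace)
  fs <- trace$fs
  if (!length(freqs)) stop("empty frequency grid")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  if (any(freqs <= 0 | freqs >= fs / 2)) stop("freqs must lie in (0, fs/2)")
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  m <- stats::nextn(2 * n, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(m - n)))
  k <- c(seq.int(0, floor(m / 2)), seq.int(-(ceiling(m / 2) - 1), -1))
  omega <- 2 * pi * fs * k / m
  W <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    s <- (w0 + sqrt(2 + w0^2)) / (4 * pi * freqs[j])
    psi <- pi^(-0.25) * sqrt(2 * pi * s * fs) * exp(-(s * omega - w0)^2 / 2)
    psi[omega <= 0] <- 0
    W[j, ] <- (stats::fft(xf * psi, inverse = TRUE) / m)[seq_len(n)]
  }
  structure(list(coeffs = W, freqs = freqs,
                 times = trace$t0 + (seq_len(n) - 1) / fs, fs = fs),
            class = "ctc_spectrogram")
}

#' Spectral coherence map between two spectrograms
#'
#' Normalized cross-correlation of the wavelet coefficients per frequency
#' and time lag,
#' \deqn{C_{xy}(f,\tau) = \frac{|\sum_i W_x^*(f,t_i) W_y(f,t_i+\tau)|}
#'   {\sqrt{\sum_i |W_x(f,t_i)|^2 \sum_i |W_y(f,t_i)|^2}}}
#' ("standard" normalization; self-coherence is exactly 1 at zero lag).
#' \code{normalization = "printed"} divides by the product of summed
#' moduli instead.
#'
#' @param spec_x,spec_y \code{ctc_spectrogram}s on a common frequency grid
#'   and equal length.
#' @param lags lag grid (s); positive lag means y trails x.
#' @param normalization "standard" or "printed".
#' @return \code{ctc_coherence}: list(values [nfreq x nlag in 0..1], freqs,
#'   lags).
#' @export
spectral_coherence <- function(spec_x, spec_y, lags = seq(-0.35, 0.35, by = 1e-3),
                               normalization = c("standard", "printed")) {
  normalization <- match.arg(normalization)
  if (!isTRUE(all.equal(spec_x$freqs, spec_y$freqs)))
    stop("spectrograms must share a common frequency grid")
  n <- ncol(spec_x$coeffs)
  if (ncol(spec_y$coeffs) != n)
    stop("spectrograms must have equal duration (sample-size bias)")
  fs <- spec_x$fs
  li <- round(lags * fs)
  m <- stats::nextn(n + max(abs(li)) + 1, c(2, 3, 5))
  vals <- matrix(0, length(spec_x$freqs), length(lags))
  warned <- FALSE
  for (j in seq_along(spec_x$freqs)) {
    a <- spec_x$coeffs[j, ]
    b <- spec_y$coeffs[j, ]
    # cross-correlation over all lags at once: cc[tau] = sum_t a*(t) b(t+tau)
    cc <- stats::fft(Conj(stats::fft(c(a, rep(0i, m - n)))) *
                       stats::fft(c(b, rep(0i, m - n))), inverse = TRUE) / m
    num <- Mod(cc[ifelse(li >= 0, li + 1, m + li + 1)])
    den <- if (normalization == "standard")
      sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
    else sum(Mod(a)) * sum(Mod(b))
    if (den == 0) {
      if (!warned) warning("zero-power frequency band; coherence set to 0")
      warned <- TRUE
      vals[j, ] <- 0
    } else {
      vals[j, ] <- pmin(num / den, 1)
    }
  }
  structure(list(values = vals, freqs = spec_x$freqs, lags = lags,
                 n_times = n), class = "ctc_coherence")
}

#' Cone of interest for pooling coherence
#'
#' @param f_max upper frequency limit (Hz, default 45: frequencies up to
#'   which the input flicker is tracked in the population output).
#' @param f_min lower frequency limit (Hz).
#' @param tau_center central lag (s); NULL lets \code{\link{pool_sc}}
#'   estimate it as the coherence-mass-weighted peak lag.
#' @return \code{ctc_cone}; the half lag width at frequency f is 7/(6 f).
#' @export
cone_of_interest <- function(f_max = 45, f_min = 4, tau_center = NULL) {
  structure(list(f_max = f_max, f_min = f_min, tau_center = tau_center),
            class = "ctc_cone")
}

#' Pool a coherence map into a single score
#'
#' Unweighted mean of C(f, tau) over the cone of interest: frequencies in
#' [f_min, f_max] and lags within 7/(6 f) of the central lag tau_xy. If the
#' cone does not fix tau_xy, it is estimated as the squared-coherence-
#' weighted mean lag within 25 ms of the peak of the band-averaged
#' coherence.
#'
#' @param map \code{ctc_coherence}. @param cone \code{\link{cone_of_interest}}.
#' @return \code{sc_bar} in [0, 1] with attribute \code{tau_center}.
#' @export
pool_sc <- function(map, cone = cone_of_interest()) {
  fsel <- map$freqs >= cone$f_min & map$freqs <= cone$f_max
  if (!any(fsel)) stop("empty cone: no frequencies within range")
  tau_c <- cone$tau_center
  if (is.null(tau_c)) {
    bavg <- colMeans(map$values[fsel, , drop = FALSE])
    pk <- map$lags[which.max(bavg)]
    w <- ifelse(abs(map$lags - pk) <= 0.025, bavg^2, 0)
    tau_c <- sum(map$lags * w) / sum(w)
  }
  mask <- outer(7 / (6 * map$freqs), rep(1, length(map$lags)))
  inside <- fsel & abs(matrix(map$lags, length(map$freqs),
                              length(map$lags), byrow = TRUE) - tau_c) <= mask
  if (!any(inside)) stop("empty cone: no grid points inside")
  structure(mean(map$values[inside]), tau_center = tau_c)
}

#' Input-signal content score of a population output
#'
#' Convenience pipeline: Morlet spectrograms of the flicker input and the
#' output trace, spectral coherence, cone pooling.
#'
#' @param output_trace population output (\code{analog_trace}, 1 kHz).
#' @param flicker \code{ctc_flicker} (or numeric 1 kHz trace) input signal.
#' @param freqs frequency grid (Hz). @param lags lag grid (s).
#' @param cone \code{\link{cone_of_interest}}.
#' @param normalization see \code{\link{spectral_coherence}}.
#' @return \code{sc_bar} value.
#' @export
sc_score <- function(output_trace, flicker,
                     freqs = seq(4, 45, by = 1),
                     lags = seq(-0.35, 0.35, by = 1e-3),
                     cone = cone_of_interest(),
                     normalization = "standard") {
  output_trace <- as_trace(output_trace)
  fin <- if (inherits(flicker, "ctc_flicker"))
    flicker_trace(flicker, output_trace$fs,
                  length(output_trace$samples) / output_trace$fs)
  else flicker
  if (length(fin) != length(output_trace$samples))
    stop("input and output must have equal duration (sample-size bias)")
  sx <- morlet_spectrogram(analog_trace(fin, output_trace$fs), freqs)
  sy <- morlet_spectrogram(output_trace, freqs)
  as.numeric(pool_sc(spectral_coherence(sx, sy, lags,
                                        normalization = normalization), cone))
}

#' Surrogate chance level for the signal-content score
#'
#' Pairs the output trace with independently generated surrogate flicker
#' signals and returns a percentile of the resulting SC-bar distribution.
#'
#' @param output_trace population output (1 kHz trace).
#' @param flicker_generator function(i) returning a surrogate
#'   \code{ctc_flicker} or numeric 1 kHz trace for surrogate index i.
#' @param n_surrogates number of surrogates (>= 100 recommended).
#' @param percentile percentile of the surrogate distribution (default 95).
#' @param ... forwarded to \code{\link{sc_score}}.
#' @return chance-level value, with the surrogate scores as attribute
#'   \code{scores}.
#' @export
chance_level <- function(output_trace, flicker_generator, n_surrogates = 100,
                         percentile = 95, ...) {
  scores <- vapply(seq_len(n_surrogates), function(i)
    sc_score(output_trace, flicker_generator(i), ...), numeric(1))
  structure(stats::quantile(scores, percentile / 100, names = FALSE),
            scores = scores)
}
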