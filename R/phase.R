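# Instantaneous gamma-phase measurement.
#
# Offline: z-score the 1 kHz analysis signal, zero-phase FIR bandpass around
# the gamma peak (forward-backward application), Hilbert analytic signal,
# phase = argument. Real-time: an autoregressive model fitted with the Burg
# lattice method forecasts the signal beyond "now" so that the Hilbert edge
# distortion (about two gamma cycles) never reaches the sample being read;
# only past data enter the estimate.

#' Bandpass specification around a spectral peak
#' @param f_peak peak frequency (Hz). @param f_lo,f_hi band edges (Hz),
#'   the half-power points on each side of the peak.
#' @export
bandpass_spec <- function(f_peak, f_lo, f_hi) {
  if (!(0 < f_lo && f_lo < f_peak && f_peak < f_hi))
    stop("need 0 < f_lo < f_peak < f_hi")
  structure(list(f_peak = f_peak, f_lo = f_lo, f_hi = f_hi),
            class = "ctc_band")
}

# analytic signal via FFT (Hilbert transform)
hilbert_analytic <- function(y) {
  n <- length(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(y) * h, inverse = TRUE) / n
}

as_trace <- function(trace) {
  if (inherits(trace, "ctc_trace")) return(trace)
  if (is.numeric(trace)) return(analog_trace(trace))
  stop("expected an analog trace")
}

# time-averaged Morlet power spectrum (vector over freqs)
morlet_avg_power <- function(x, fs, freqs) {
  sp <- morlet_spectrogram(analog_trace(x, fs), freqs)
  rowMeans(Mod(sp$coeffs)^2)
}

#' Locate the gamma band of a population signal
#'
#' Computes a time-averaged Morlet power spectrum, finds the gamma peak in
#' \code{search} (20-120 Hz) after light smoothing (3-bin running mean; ties
#' broken toward the lower frequency), and returns the band delimited by the
#' half-power points on each side of the peak.
#'
#' @param trace \code{\link{analog_trace}} (or numeric vector at 1 kHz) of
#'   at least 1 s.
#' @param search numeric(2), peak search range (Hz).
#' @param f_step spectral resolution (Hz).
#' @return \code{\link{bandpass_spec}}.
#' @export
estimate_gamma_band <- function(trace, search = c(20, 120), f_step = 1) {
  trace <- as_trace(trace)
  if (length(trace$samples) < trace$fs) stop("need at least 1 s of signal")
  freqs <- seq(max(4, search[1] / 2), min(search[2] + 20, trace$fs / 2 - 1),
               by = f_step)
  p <- morlet_avg_power(zscore(trace$samples), trace$fs, freqs)
  psm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
  psm[is.na(psm)] <- p[is.na(psm)]
  sel <- which(freqs >= search[1] & freqs <= search[2])
  pk <- sel[which.max(psm[sel])]
  if (pk == sel[1] || pk == sel[length(sel)])
    stop("no gamma peak: spectrum is monotone over the search band")
  half <- psm[pk] / 2
  below <- which(freqs < freqs[pk] & psm <= half)
  above <- which(freqs > freqs[pk] & psm <= half)
  f_lo <- if (length(below)) freqs[max(below)] else freqs[pk] / 2
  f_hi <- if (length(above)) freqs[min(above)]
          else min(2 * freqs[pk] - f_lo, trace$fs / 2 - 1)
  bandpass_spec(freqs[pk], f_lo, f_hi)
}

# zero-phase FIR bandpass: linear-phase design (Hamming), applied
# forward-backward so the net filter has exactly zero phase
bandpass_zero_phase <- function(x, band, fs) {
  ord <- round(3 * fs / band$f_lo)
  if (ord %% 2 == 1) ord <- ord + 1   # even order -> odd-length symmetric FIR
  ord <- min(ord, floor((length(x) - 1) / 3))
  w <- c(band$f_lo, band$f_hi) / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) stop("band exceeds the Nyquist range")
  h <- as.numeric(signal::fir1(ord, w, type = "pass"))
  # two passes of the symmetric (linear-phase) FIR via FFT, with the total
  # group delay (= ord samples, an integer) compensated exactly: identical
  # to forward-backward filtering away from the edges
  n <- length(x)
  L <- length(h)
  m <- stats::nextn(n + 2 * L, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(m - L)))
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) * H * H,
                     inverse = TRUE) / m)
  y[(L - 1) + seq_len(n)]
}

#' Offline instantaneous phase (Hilbert method)
#'
#' Normalizes the trace (z-score), zeroes artifact windows, applies the
#' zero-phase FIR bandpass given by \code{band}, and reads the instantaneous
#' phase as the argument of the Hilbert analytic signal. Samples within
#' \code{guard} (30 ms, about two gamma cycles) of the trace edges or of an
#' artifact window are masked invalid.
#'
#' @param trace \code{\link{analog_trace}} or numeric vector (1 kHz).
#' @param band \code{\link{bandpass_spec}}.
#' @param artifact_windows list of numeric(2) time windows (s, relative to
#'   trace start) to zero out before filtering (e.g. stimulation artifacts).
#' @param guard edge/artifact guard band (s).
#' @return object of class \code{ctc_phase}: list(phase, fs, valid, t0);
#'   phase in (-pi, pi].
#' @export
offline_phase <- function(trace, band, artifact_windows = list(),
                          guard = 0.03) {
  trace <- as_trace(trace)
  fs <- trace$fs
  x <- zscore(trace$samples)
  n <- length(x)
  valid <- rep(TRUE, n)
  g <- round(guard * fs)
  for (w in artifact_windows) {
    i0 <- max(1, floor(w[1] * fs) + 1)
    i1 <- min(n, ceiling(w[2] * fs) + 1)
    if (i1 >= i0) {
      x[i0:i1] <- 0
      valid[max(1, i0 - g):min(n, i1 + g)] <- FALSE
    }
  }
  y <- bandpass_zero_phase(x, band, fs)
  ph <- Arg(hilbert_analytic(y))
  if (g >= 1) {
    valid[seq_len(min(g, n))] <- FALSE
    valid[seq.int(max(1, n - g + 1), n)] <- FALSE
  }
  structure(list(phase = wrap_angle(ph), fs = fs, valid = valid,
                 t0 = trace$t0), class = "ctc_phase")
}

#' @export
print.ctc_phase <- function(x, ...) {
  cat("<ctc_phase>", length(x$phase), "samples at", x$fs, "Hz;",
      sum(!x$valid), "masked\n")
  invisible(x)
}

# phase value at a time point (s relative to t0); NA if masked
phase_at <- function(ph, t) {
  i <- round((t - ph$t0) * ph$fs) + 1
  if (i < 1 || i > length(ph$phase) || !ph$valid[i]) return(NA_real_)
  ph$phase[i]
}

#' Fit an autoregressive forecasting model (Burg lattice method)
#'
#' @param trace training signal (unperturbed activity; \code{analog_trace}
#'   or numeric vector). Z-scored internally.
#' @param order model order p; the default (\code{fs / f_peak} if a band is
#'   given, else 15) spans one oscillation cycle at 1 kHz.
#' @param band optional \code{\link{bandpass_spec}}; stored with the model
#'   and used to pick the default order.
#' @return object of class \code{ctc_ar}: order, coeffs, intercept,
#'   noise_std, band.
#' @export
fit_ar <- function(trace, order = NULL, band = NULL) {
  trace <- as_trace(trace)
  x <- zscore(trace$samples)
  order <- order %||% if (!is.null(band)) round(trace$fs / band$f_peak) else 15
  if (order < 1) stop("order must be at least 1")
  if (order >= length(x)) stop("order must be smaller than the trace length")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  structure(list(order = order, coeffs = as.numeric(fit$ar),
                 intercept = fit$x.mean * (1 - sum(fit$ar)),
                 noise_std = sqrt(fit$var.pred), band = band),
            class = "ctc_ar")
}

#' @export
print.ctc_ar <- function(x, ...) {
  cat("<ctc_ar> order", x$order, "| residual sd", signif(x$noise_std, 3), "\n")
  invisible(x)
}

# forecast an AR model h steps beyond the (z-scored) history
ar_forecast <- function(model, z, h) {
  p <- model$order
  x <- c(z, numeric(h))
  n0 <- length(z)
  cf <- model$coeffs
  for (k in seq_len(h)) {
    i <- n0 + k
    x[i] <- model$intercept + sum(cf * x[i - seq_len(p)])
  }
  x
}

#' Real-time instantaneous phase (AR forecast + Hilbert)
#'
#' Estimates the phase at the last sample of \code{history} using only data
#' up to that sample: the AR model extends the signal \code{horizon} seconds
#' into the future, the extended signal is band-passed and Hilbert-
#' transformed, and the phase is read at the history end, now at least
#' \code{horizon} away from the forecast edge so edge distortion does not
#' reach it.
#'
#' @param model \code{\link{fit_ar}} model (trained on unperturbed data).
#' @param history numeric vector or \code{analog_trace}: the signal up to
#'   "now" (>= 0.2 s recommended; must exceed the AR order).
#' @param band \code{\link{bandpass_spec}}; defaults to the band stored in
#'   the model.
#' @param horizon forecast length (s), >= 0.05.
#' @param read_offset samples beyond the history end at which to read the
#'   phase (0 = the last history sample). Used to read the phase at a pulse
#'   onset from history truncated just before it, so that no sample
#'   containing the pulse response enters the estimate.
#' @param artifacts list of sample-index ranges c(i0, i1) within the
#'   history to zero out before filtering (earlier pulse responses).
#' @return phase at the history end (radians), or NA if masked.
#' @export
realtime_phase <- function(model, history, band = model$band,
                           horizon = 0.1, read_offset = 0,
                           artifacts = list()) {
  history <- as_trace(history)
  fs <- history$fs
  if (is.null(band)) stop("no bandpass specification available")
  if (horizon < 0.05) stop("horizon must be at least 50 ms (>= 3 gamma cycles)")
  z <- zscore(history$samples)
  for (a in artifacts) {
    i0 <- max(1, a[1]); i1 <- min(length(z), a[2])
    if (i1 >= i0) z[i0:i1] <- 0
  }
  if (length(z) <= model$order)
    stop("history shorter than the AR model order")
  h <- round(horizon * fs)
  x <- ar_forecast(model, z, h)
  if (!all(is.finite(x)) || max(abs(x[-seq_along(z)])) > 50)
    stop("AR forecast diverged; model does not match the signal")
  ph <- offline_phase(analog_trace(x, fs), band)
  i <- length(z) + read_offset
  if (i < 1 || i > length(ph$phase) || !ph$valid[i]) return(NA_real_)
  ph$phase[i]
}

#' Circular statistics of a set of angles
#'
#' @param angles radians. @param weights optional non-negative weights.
#' @return list: \code{mean} (argument of the mean resultant vector),
#'   \code{resultant} (mean resultant length in [0, 1]), \code{q25},
#'   \code{q75} (circular percentiles about the mean), \code{undefined}
#'   (TRUE when the resultant length is below 1e-9).
#' @export
circular_stats <- function(angles, weights = NULL) {
  if (!length(angles)) stop("empty angle set")
  w <- weights %||% rep(1, length(angles))
  z <- sum(w * exp(1i * angles)) / sum(w)
  r <- Mod(z)
  if (r < 1e-9)
    return(list(mean = NA_real_, resultant = r, q25 = NA_real_,
                q75 = NA_real_, undefined = TRUE))
  m <- Arg(z)
  dev <- wrap_angle(angles - m)
  if (is.null(weights)) {
    q <- stats::quantile(dev, c(0.25, 0.75), names = FALSE)
  } else {
    o <- order(dev)
    cw <- cumsum(w[o]) / sum(w)
    q <- c(dev[o][which.max(cw >= 0.25)], dev[o][which.max(cw >= 0.75)])
  }
  list(mean = m, resultant = r, q25 = wrap_angle(m + q[1]),
       q75 = wrap_angle(m + q[2]), undefined = FALSE)
}

#' Default phase-analysis signal of a population
#'
#' The 1 kHz excitatory-pool rate, smoothed with a 3 ms boxcar. Synaptic
#' current components are available through
#' \code{\link{extract_population_signal}} as alternatives.
#'
#' @param result \code{ctc_result}. @param population population id.
#' @param component signal component, default "exc_rate".
#' @return \code{\link{analog_trace}}.
#' @export
analysis_signal <- function(result, population, component = "exc_rate") {
  tr <- extract_population_signal(result, population, component)
  analog_trace(boxcar3(tr$samples), tr$fs, tr$t0)
}

# centered 3-sample boxcar
boxcar3 <- function(x) {
  y <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  y[1] <- mean(x[1:2])
  y[length(x)] <- mean(x[(length(x) - 1):length(x)])
  as.numeric(y)
}
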