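# Stochastic inputs: per-neuron 1/f (pink) noise and the piecewise-constant
# uniform "flicker" amplitude modulation carried by the afferent drive.

#' Generate a unit-variance 1/f (pink) noise trace
#'
#' Streams white noise through a bank of six one-pole filters plus direct
#' terms whose summed response approximates a 1/f power spectrum over the
#' resolvable band; the same filter drives every neuron's private noise
#' inside the simulator. The returned trace is normalized to zero mean and
#' unit sample standard deviation.
#'
#' @param n_samples number of samples (> 1).
#' @param dt sample interval (s); recorded as an attribute (the filter shape
#'   is defined in normalized frequency).
#' @param seed integer seed; the same seed reproduces the same trace.
#' @return numeric vector of length \code{n_samples} with attributes
#'   \code{dt} and \code{seed}.
#' @export
generate_pink_noise <- function(n_samples, dt = 1e-4, seed = 1) {
  if (n_samples <= 1) stop("n_samples must exceed 1")
  x <- .pink_noise_cpp(as.integer(n_samples), as.double(seed), 0)
  x <- (x - mean(x)) / stats::sd(x)
  attr(x, "dt") <- dt
  attr(x, "seed") <- seed
  x
}

#' Generate a flicker signal
#'
#' Independent Uniform[-1, 1] draws, each held for one \code{step} window
#' (10 ms by default, emulating a 100 frames/s luminance flicker). The
#' flicker is the information-carrying amplitude modulation of the afferent
#' drive that coherence analysis tracks through the network.
#'
#' @param duration total signal duration (s).
#' @param step hold duration of each value (s).
#' @param seed integer seed.
#' @return object of class \code{ctc_flicker}: list with \code{values}
#'   (one draw per window), \code{step} and \code{seed}.
#' @export
generate_flicker <- function(duration, step = 0.01, seed = 1) {
  if (step <= 0 || duration < step) stop("need duration >= step > 0")
  n <- ceiling(duration / step)
  vals <- with_local_seed(seed, stats::runif(n, -1, 1))
  structure(list(values = vals, step = step, seed = seed),
            class = "ctc_flicker")
}

#' Expand a flicker signal to an evenly sampled trace
#'
#' @param flicker \code{ctc_flicker}.
#' @param fs target sampling rate (Hz).
#' @param duration optional duration (s), default the flicker's extent.
#' @return numeric vector sampled at \code{fs}.
#' @export
flicker_trace <- function(flicker, fs = 1000, duration = NULL) {
  duration <- duration %||% (length(flicker$values) * flicker$step)
  n <- round(duration * fs)
  idx <- pmin(floor((seq_len(n) - 1) / fs / flicker$step) + 1,
              length(flicker$values))
  flicker$values[idx]
}
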