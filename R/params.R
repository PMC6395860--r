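# Parameter containers for the QIF column model.
#
# All quantities are SI (volts, amperes, farads, seconds) internally; the
# documented defaults reproduce the standard parameterization of a cortical
# column oscillating in the gamma range through an ING mechanism.

#' Neuron population parameters
#'
#' Parameters of one cortical column's neuron populations (800 excitatory,
#' 200 inhibitory conductance-based quadratic integrate-and-fire units by
#' default). The quadratic membrane current is \eqn{p_2 V^2 + p_1 V + p_0};
#' its stable root (about -64.7 mV with the defaults) is the quiescent
#' resting potential. Membrane capacitance per neuron is
#' \code{cm_specific * area} (1 uF/cm^2 specific capacitance).
#'
#' @param id population identifier (single short string, e.g. "X").
#' @param n_exc,n_inh pool sizes.
#' @param area_exc,area_inh membrane areas (cm^2).
#' @param cm_specific specific membrane capacitance (F/cm^2).
#' @param p0,p1,p2 quadratic membrane-current coefficients (A, A/V, A/V^2).
#' @param V_e,V_i excitatory / inhibitory reversal potentials (V).
#' @param V_thresh spike threshold (V). @param V_reset reset potential (V).
#' @param sigma_n magnitude of the per-neuron unit-variance 1/f noise
#'   current (A); 0 disables noise.
#' @return object of class \code{ctc_population}.
#' @export
population_params <- function(id,
                              n_exc = 800, n_inh = 200,
                              area_exc = 2.88e-4, area_inh = 1.2e-4,
                              cm_specific = 1e-6,
                              p0 = 3.89e-9, p1 = 1.30e-7, p2 = 1.08e-6,
                              V_e = 0, V_i = -75e-3,
                              V_thresh = -56.23e-3, V_reset = -67e-3,
                              sigma_n = 0) {
  stopifnot(is.character(id), length(id) == 1L)
  if (n_exc <= 0 || n_inh <= 0) stop("pool sizes must be positive")
  if (area_exc <= 0 || area_inh <= 0) stop("membrane areas must be positive")
  if (cm_specific <= 0) stop("specific capacitance must be positive")
  if (V_reset >= V_thresh) stop("V_reset must lie below V_thresh")
  if (sigma_n < 0) stop("sigma_n must be non-negative")
  structure(list(id = id, n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 area_exc = area_exc, area_inh = area_inh,
                 cm_specific = cm_specific,
                 p0 = p0, p1 = p1, p2 = p2, V_e = V_e, V_i = V_i,
                 V_thresh = V_thresh, V_reset = V_reset, sigma_n = sigma_n),
            class = "ctc_population")
}

#' Synaptic kernel parameters
#'
#' Exponential synaptic kernels: an excitatory event adds weight \code{w_e}
#' decaying with \code{tau_e}; an inhibitory event adds a fast/slow mixture
#' (\code{chi1} at \code{tau_i1}, \code{chi2} at \code{tau_i2}) of total
#' weight \code{w_i}. Kernel state is converted to current as
#' \eqn{g(t) (V_{rev} - V)/|V_{rev} - V_{reset}|}, so a unit event delivers
#' exactly the nominal weight in amperes at the reset potential while
#' retaining reversal behavior.
#'
#' @param w_e,w_i synaptic weights (A).
#' @param tau_e excitatory decay (s). @param tau_i1,tau_i2 fast/slow
#'   inhibitory decays (s). @param chi1,chi2 mixture fractions (sum to 1).
#' @return object of class \code{ctc_synapses}.
#' @export
synapse_params <- function(w_e = 0.4e-9, w_i = 1.2e-9,
                           tau_e = 3e-3, tau_i1 = 1.2e-3, tau_i2 = 8e-3,
                           chi1 = 0.9, chi2 = 0.1) {
  if (any(c(tau_e, tau_i1, tau_i2) <= 0)) stop("synaptic taus must be positive")
  if (abs(chi1 + chi2 - 1) > 1e-9) stop("chi1 + chi2 must equal 1")
  if (w_e <= 0 || w_i <= 0) stop("synaptic weights must be positive")
  structure(list(w_e = w_e, w_i = w_i, tau_e = tau_e,
                 tau_i1 = tau_i1, tau_i2 = tau_i2, chi1 = chi1, chi2 = chi2),
            class = "ctc_synapses")
}

#' Projection between neuron pools
#'
#' @param source_pop,target_pop population ids.
#' @param source_pool,target_pool "exc" or "inh".
#' @param prob connection probability in [0, 1] (independent Bernoulli draws
#'   per source/target pair, no autapses).
#' @param delay conduction delay (s); rounded to an integer multiple of the
#'   integration step, minimum one step.
#' @param kind "excitatory" or "inhibitory"; must match the source pool.
#' @return object of class \code{ctc_projection}.
#' @export
projection <- function(source_pop, source_pool, target_pop, target_pool,
                       prob, delay, kind) {
  source_pool <- match.arg(source_pool, c("exc", "inh"))
  target_pool <- match.arg(target_pool, c("exc", "inh"))
  kind <- match.arg(kind, c("excitatory", "inhibitory"))
  if (prob < 0 || prob > 1) stop("connection probability must lie in [0, 1]")
  if (delay < 0) stop("delay must be non-negative")
  if ((source_pool == "inh") != (kind == "inhibitory"))
    stop("projection kind must match the source pool")
  structure(list(source_pop = source_pop, source_pool = source_pool,
                 target_pop = target_pop, target_pool = target_pool,
                 prob = prob, delay = delay, kind = kind),
            class = "ctc_projection")
}

#' Afferent drive specification
#'
#' Each neuron of a driven pool receives an independent inhomogeneous
#' Poisson event train with instantaneous rate
#' \eqn{S(t) = S_0 (1 + \sigma_F F(t))}, where F is the column's flicker
#' signal (piecewise-constant Uniform[-1,1], one value per 10 ms window by
#' default). Events feed the excitatory synaptic kernel with weight
#' \code{w_e} at zero delay.
#'
#' @param rate_exc,rate_inh base rates \eqn{S_0} for the excitatory and
#'   inhibitory pool (events/s per neuron).
#' @param sigma_f flicker modulation strength (dimensionless, <= 1).
#' @param flicker optional \code{\link{generate_flicker}} signal shared by
#'   both pools; if NULL one is generated at simulation time from the
#'   simulation seed.
#' @param flicker_step flicker hold duration (s).
#' @return object of class \code{ctc_drive}.
#' @export
drive_spec <- function(rate_exc, rate_inh, sigma_f = 0.1,
                       flicker = NULL, flicker_step = 0.01) {
  if (rate_exc < 0 || rate_inh < 0) stop("base rates must be non-negative")
  if (sigma_f < 0 || sigma_f > 1) stop("sigma_f must lie in [0, 1]")
  structure(list(rate_exc = rate_exc, rate_inh = rate_inh, sigma_f = sigma_f,
                 flicker = flicker, flicker_step = flicker_step),
            class = "ctc_drive")
}

#' Stimulation pulse
#'
#' A square current pulse injected additively into every neuron (both
#' pools) of the target column, emulating intracortical microstimulation.
#'
#' @param target population id.
#' @param amplitude signed current (A); positive depolarizes.
#' @param onset pulse onset time (s).
#' @param duration pulse duration (s), default 1 ms.
#' @return object of class \code{ctc_pulse}.
#' @export
stimulation_pulse <- function(target, amplitude, onset, duration = 1e-3) {
  if (duration <= 0) stop("pulse duration must be positive")
  if (onset < 0) stop("pulse onset must be non-negative")
  structure(list(target = target, amplitude = amplitude,
                 onset = onset, duration = duration), class = "ctc_pulse")
}

# Calibrated drive base rates (events/s) and Z connection probabilities per
# internal noise level, produced by calibrate_drives()/calibrate_z_connectivity()
# with the default targets (15 Hz exc / 60 Hz inh). These serve as starting
# points; calibration converges in a couple of iterations from them.
.default_calibrations <- list(
  column = list(
    "0"     = c(rate_exc = 3400, rate_inh = 3386),
    "0.075" = c(rate_exc = 3402, rate_inh = 3637),
    "0.1"   = c(rate_exc = 3320, rate_inh = 3640),
    "0.15"  = c(rate_exc = 3158, rate_inh = 3643),
    "0.175" = c(rate_exc = 3014, rate_inh = 3597)
  ),
  xyz = list(
    "0"     = c(p_ze = 0.1353, p_zi = 0.1338, rate_exc = 3382, rate_inh = 3073),
    "0.075" = c(p_ze = 0.1300, p_zi = 0.1350, rate_exc = 3274, rate_inh = 3108),
    "0.1"   = c(p_ze = 0.1264, p_zi = 0.1348, rate_exc = 3291, rate_inh = 3222),
    "0.15"  = c(p_ze = 0.1218, p_zi = 0.1366, rate_exc = 3119, rate_inh = 3252),
    "0.175" = c(p_ze = 0.1188, p_zi = 0.1356, rate_exc = 3010, rate_inh = 3223)
  )
)

#' Default calibrated drive rates for a noise level
#'
#' Looks up the stored calibration nearest to \code{noise_level} (nA scale
#' in the stored keys; argument in amperes).
#'
#' @param noise_level sigma_n in amperes.
#' @param what "column" (drive rates) or "xyz" (Z connection probabilities).
#' @return named numeric vector.
#' @export
default_calibration <- function(noise_level, what = c("column", "xyz")) {
  what <- match.arg(what)
  tab <- .default_calibrations[[what]]
  keys <- as.numeric(names(tab)) * 1e-9
  tab[[which.min(abs(keys - noise_level))]]
}
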