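# Network configuration builders: a single ING column, a laterally coupled
# pair of independent columns (synchronization task), and the bistable
# three-column XYZ routing network.

#' Assemble a network configuration
#'
#' @param populations list of \code{\link{population_params}}.
#' @param synapses \code{\link{synapse_params}}.
#' @param projections list of \code{\link{projection}}.
#' @param drives named list (population id -> \code{\link{drive_spec}}).
#' @param dt forward-Euler integration step (s).
#' @param seed integer master seed; connectivity, per-neuron noise, Poisson
#'   and flicker streams are derived from it by fixed sub-seeding.
#' @param syn_norm synaptic current normalization. "volt" (default) takes
#'   the conductance-times-driving-force product literally in SI units,
#'   current = \eqn{g (V_{rev}-V) \cdot 1\,\mathrm{V}^{-1}}; synaptic
#'   currents are then a few hundred pA, which places the documented noise
#'   magnitudes (0.075-0.15 nA) and pulse amplitudes (0.25-4 nA) on the
#'   scale at which they visibly perturb and fully reset the rhythm.
#'   "common" rescales both kernel types by \eqn{1/|V_e - V_{reset}|} so a
#'   synaptic event delivers its nominal weight in amperes near rest;
#'   "per_reversal" divides each kernel by its own \eqn{|V_{rev}-V_{reset}|}
#'   (effective inhibition ~8x stronger; the rhythm slows below the gamma
#'   band).
#' @return object of class \code{ctc_config}.
#' @export
network_config <- function(populations, synapses, projections, drives,
                           dt = 1e-4, seed = 1,
                           syn_norm = c("volt", "common", "per_reversal")) {
  syn_norm <- match.arg(syn_norm)
  if (dt <= 0) stop("dt must be positive")
  ids <- vapply(populations, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("population ids must be unique")
  for (pr in projections) {
    if (!(pr$source_pop %in% ids) || !(pr$target_pop %in% ids))
      stop("projection endpoint references unknown population")
    steps <- pr$delay / dt
    if (abs(steps - round(steps)) > 1e-6)
      warning("projection delay is not an integer multiple of dt; rounding")
  }
  if (!all(names(drives) %in% ids)) stop("drive references unknown population")
  structure(list(populations = populations, synapses = synapses,
                 projections = projections, drives = drives,
                 dt = dt, seed = as.integer(seed), syn_norm = syn_norm),
            class = "ctc_config")
}

#' @export
print.ctc_config <- function(x, ...) {
  ids <- vapply(x$populations, `[[`, "", "id")
  cat("<ctc_config> populations:", paste(ids, collapse = ", "),
      "| projections:", length(x$projections),
      "| dt:", format(x$dt), "s | seed:", x$seed, "\n")
  invisible(x)
}

# local ING wiring of one column: dense inhibitory projections I->I and I->E
local_projections <- function(id, p_loc = 0.5, tau_loc = 5e-3) {
  list(projection(id, "inh", id, "inh", p_loc, tau_loc, "inhibitory"),
       projection(id, "inh", id, "exc", p_loc, tau_loc, "inhibitory"))
}

#' Build a single cortical column
#'
#' One ING oscillator: 800 excitatory and 200 inhibitory QIF neurons with
#' inhibitory-to-inhibitory and inhibitory-to-excitatory projections
#' (probability 0.5, delay 5 ms) and afferent Poisson drive to both pools.
#' The mutual inhibition plus delay generates gamma-band population
#' oscillations (60 Hz at zero noise with calibrated drives).
#'
#' @param params \code{\link{population_params}} template (the \code{id} and
#'   \code{sigma_n} fields are overridden); NULL for defaults.
#' @param synapses \code{\link{synapse_params}}; NULL for defaults.
#' @param noise_level internal 1/f noise magnitude sigma_n (A).
#' @param seed master seed.
#' @param drive_rates named vector \code{c(rate_exc=, rate_inh=)}; NULL uses
#'   the stored calibration for this noise level.
#' @param sigma_f flicker modulation strength.
#' @param id population id, default "col".
#' @return \code{ctc_config}.
#' @export
build_single_column <- function(params = NULL, synapses = NULL,
                                noise_level = 0.075e-9, seed = 1,
                                drive_rates = NULL, sigma_f = 0.1,
                                id = "col") {
  if (noise_level < 0) stop("noise_level must be non-negative")
  params <- params %||% population_params(id)
  params$id <- id
  params$sigma_n <- noise_level
  synapses <- synapses %||% synapse_params()
  drive_rates <- drive_rates %||% default_calibration(noise_level, "column")
  drives <- list(drive_spec(drive_rates[["rate_exc"]],
                            drive_rates[["rate_inh"]], sigma_f = sigma_f))
  names(drives) <- id
  network_config(list(params), synapses, local_projections(id),
                 drives, seed = seed)
}

#' Build two independent columns (synchronization task)
#'
#' Two uncoupled copies of the single column, ids "X" and "Y", each with its
#' own afferent drive and flicker. Used by the PRC-based synchronization
#' controller.
#'
#' @inheritParams build_single_column
#' @return \code{ctc_config}.
#' @export
build_column_pair <- function(params = NULL, synapses = NULL,
                              noise_level = 0.075e-9, seed = 1,
                              drive_rates = NULL, sigma_f = 0.1) {
  drive_rates <- drive_rates %||% default_calibration(noise_level, "column")
  pops <- lapply(c("X", "Y"), function(id) {
    p <- params %||% population_params(id)
    p$id <- id; p$sigma_n <- noise_level
    p
  })
  drives <- list(
    X = drive_spec(drive_rates[["rate_exc"]], drive_rates[["rate_inh"]],
                   sigma_f = sigma_f),
    Y = drive_spec(drive_rates[["rate_exc"]], drive_rates[["rate_inh"]],
                   sigma_f = sigma_f))
  network_config(pops, synapses %||% synapse_params(),
                 c(local_projections("X"), local_projections("Y")),
                 drives, seed = seed)
}

#' Build the bistable XYZ routing network
#'
#' Three columns: X and Y (input layer, each driven by its own flicker-
#' modulated afferent signal) are coupled laterally through excitatory
#' projections onto each other's inhibitory pool (X_e -> Y_i and Y_e -> X_i,
#' probability \code{p_xy} = 0.02, delay 5 ms), which locks them in
#' anti-phase. Both project with equal strength onto the output column Z
#' (X_e/Y_e -> Z_e with probability \code{p_ze}, -> Z_i with \code{p_zi}).
#' Z sends no feedback and receives no afferent drive by default (its input
#' is the convergent feedforward drive); the competition between X and Y to
#' entrain Z makes the network bistable between the routing states Tr^X and
#' Tr^Y.
#'
#' @param column_params \code{\link{population_params}} template; NULL for
#'   defaults.
#' @param p_ze,p_zi feedforward connection probabilities onto Z's pools;
#'   NULL uses the stored calibration for this noise level.
#' @param seed master seed.
#' @param noise_level sigma_n (A), applied to all three columns.
#' @param synapses \code{\link{synapse_params}}; NULL for defaults.
#' @param drive_rates named vector for the X/Y afferent drives; NULL uses
#'   the stored calibration.
#' @param sigma_f flicker strength for the X and Y input signals.
#' @param p_xy,tau_xy lateral coupling probability and delay.
#' @param tau_z delay of the feedforward projections onto Z (s).
#' @param z_drive_rates optional named vector giving Z afferent base rates
#'   (default none).
#' @return \code{ctc_config}.
#' @export
build_xyz_network <- function(column_params = NULL, p_ze = NULL, p_zi = NULL,
                              seed = 1, noise_level = 0.075e-9,
                              synapses = NULL, drive_rates = NULL,
                              sigma_f = 0.1, p_xy = 0.02, tau_xy = 5e-3,
                              tau_z = 5e-3, z_drive_rates = c(0, 0)) {
  zcal <- default_calibration(noise_level, "xyz")
  p_ze <- p_ze %||% zcal[["p_ze"]]
  p_zi <- p_zi %||% zcal[["p_zi"]]
  if (p_ze < 0 || p_ze > 1 || p_zi < 0 || p_zi > 1)
    stop("p_ze and p_zi must lie in [0, 1]")
  drive_rates <- drive_rates %||%
    zcal[c("rate_exc", "rate_inh")] %||%
    default_calibration(noise_level, "column")
  pops <- lapply(c("X", "Y", "Z"), function(id) {
    p <- column_params %||% population_params(id)
    p$id <- id; p$sigma_n <- noise_level
    p
  })
  projs <- c(local_projections("X"), local_projections("Y"),
             local_projections("Z"),
             list(projection("X", "exc", "Y", "inh", p_xy, tau_xy, "excitatory"),
                  projection("Y", "exc", "X", "inh", p_xy, tau_xy, "excitatory"),
                  projection("X", "exc", "Z", "exc", p_ze, tau_z, "excitatory"),
                  projection("Y", "exc", "Z", "exc", p_ze, tau_z, "excitatory"),
                  projection("X", "exc", "Z", "inh", p_zi, tau_z, "excitatory"),
                  projection("Y", "exc", "Z", "inh", p_zi, tau_z, "excitatory")))
  drives <- list(
    X = drive_spec(drive_rates[["rate_exc"]], drive_rates[["rate_inh"]],
                   sigma_f = sigma_f),
    Y = drive_spec(drive_rates[["rate_exc"]], drive_rates[["rate_inh"]],
                   sigma_f = sigma_f),
    Z = drive_spec(z_drive_rates[[1]], z_drive_rates[[2]], sigma_f = 0))
  network_config(pops, synapses %||% synapse_params(), projs, drives,
                 seed = seed)
}
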