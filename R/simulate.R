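# Simulation driver: batch runs and an incremental session API used by the
# closed-loop controllers (step the network 1 ms at a time, inject pulses at
# runtime, read recent population signals).

# lower a ctc_config + resolved flickers into the C++ constructor format
lower_config <- function(config, flickers, sim_seed) {
  drv <- lapply(names(config$drives), function(id) {
    d <- config$drives[[id]]
    fl <- flickers[[id]]
    list(rate_exc = d$rate_exc, rate_inh = d$rate_inh, sigma_f = d$sigma_f,
         flicker = if (is.null(fl)) numeric(0) else fl$values,
         flicker_step = d$flicker_step)
  })
  names(drv) <- names(config$drives)
  list(populations = lapply(config$populations, unclass),
       synapses = unclass(config$synapses),
       projections = lapply(config$projections, unclass),
       drives = drv, dt = config$dt, seed = as.double(config$seed),
       sim_seed = as.double(sim_seed),
       syn_norm = config$syn_norm %||% "volt")
}

# deterministic flicker sub-seeds per population
resolve_flickers <- function(config, duration, sim_seed) {
  ids <- names(config$drives)
  fl <- vector("list", length(ids))
  names(fl) <- ids
  for (k in seq_along(ids)) {
    d <- config$drives[[k]]
    if (d$sigma_f > 0 && (d$rate_exc > 0 || d$rate_inh > 0)) {
      fl[[k]] <- d$flicker %||%
        generate_flicker(duration + d$flicker_step, d$flicker_step,
                         seed = sim_seed * 131 + 7919 * k)
    }
  }
  fl
}

#' Open an incremental simulation session
#'
#' Creates the network state (connectivity, kernel states, per-neuron noise
#' and Poisson streams) without advancing time. Use
#' \code{\link{session_step}} to integrate, \code{\link{session_add_pulse}}
#' to inject stimulation pulses at runtime (closed loop), and
#' \code{\link{collect_result}} to retrieve spikes and signals.
#'
#' @param config \code{ctc_config}.
#' @param duration maximum duration the session will be stepped to (s);
#'   fixes the extent of the generated flicker signals.
#' @param seed realization seed for noise/Poisson/flicker streams; defaults
#'   to the config seed. Connectivity always derives from the config seed.
#' @return object of class \code{ctc_session}.
#' @export
sim_session <- function(config, duration, seed = config$seed) {
  stopifnot(inherits(config, "ctc_config"), duration > 0)
  flickers <- resolve_flickers(config, duration, seed)
  ptr <- .sim_create(lower_config(config, flickers, seed))
  structure(list(ptr = ptr, config = config, duration = duration,
                 flickers = flickers, seed = seed,
                 pulses = new.env(parent = emptyenv())),
            class = "ctc_session")
}

#' Advance a session
#' @param session \code{ctc_session}. @param n_ms whole milliseconds to integrate.
#' @export
session_step <- function(session, n_ms) {
  .sim_step(session$ptr, as.integer(n_ms))
  invisible(session)
}

#' Current session time (s)
#' @param session \code{ctc_session}.
#' @export
session_time <- function(session) .sim_time(session$ptr)

#' Schedule a stimulation pulse in a session
#' @param session \code{ctc_session}. @param pulse \code{\link{stimulation_pulse}}.
#' @export
session_add_pulse <- function(session, pulse) {
  stopifnot(inherits(pulse, "ctc_pulse"))
  .sim_add_pulse(session$ptr, pulse$target, pulse$amplitude,
                 pulse$onset, pulse$duration)
  n <- length(ls(session$pulses))
  assign(sprintf("p%06d", n + 1), pulse, envir = session$pulses)
  invisible(session)
}

#' Read the tail of a 1 kHz population signal from a running session
#'
#' @param session \code{ctc_session}.
#' @param population population id.
#' @param component "exc_rate", "inh_rate", or a current source key such as
#'   "drive", "X_exc", "Z_inh".
#' @param n_ms number of most recent 1 ms samples to return.
#' @export
session_tail <- function(session, population, component, n_ms) {
  .sim_signal_tail(session$ptr, population, component, as.integer(n_ms))
}

#' Collect the results of a session
#'
#' @param session \code{ctc_session}.
#' @return \code{ctc_result}: list with \code{spikes} (data.frame: time,
#'   population, pool, neuron), \code{signals_1khz} (per population:
#'   exc_rate, inh_rate and summed synaptic current per source into the
#'   excitatory pool), \code{flickers}, \code{pulses_applied} and
#'   \code{duration} (s).
#' @export
collect_result <- function(session) {
  sp <- .sim_spikes(session$ptr)
  pulses <- mget(sort(ls(session$pulses)), envir = session$pulses)
  structure(list(
    spikes = data.frame(time = sp$time, population = sp$population,
                        pool = sp$pool, neuron = sp$neuron),
    signals_1khz = .sim_signals(session$ptr),
    flickers = session$flickers,
    pulses_applied = unname(pulses),
    duration = session_time(session),
    config = session$config, seed = session$seed), class = "ctc_result")
}

#' Simulate a network
#'
#' Integrates the network with forward Euler at the configured step
#' (0.1 ms), recording every spike and the 1 kHz population analysis
#' signals (pool firing rates and per-source synaptic currents into each
#' excitatory pool).
#'
#' @param config \code{ctc_config}.
#' @param duration simulated time (s).
#' @param pulses list of \code{\link{stimulation_pulse}}.
#' @param seed realization seed (noise, Poisson, flicker); defaults to the
#'   config seed. Two calls with identical config, pulses and seed produce
#'   identical spike rasters.
#' @return \code{ctc_result}, see \code{\link{collect_result}}.
#' @export
simulate_network <- function(config, duration, pulses = list(),
                             seed = config$seed) {
  if (duration <= 0) stop("duration must be positive")
  sess <- sim_session(config, duration, seed)
  for (p in pulses) {
    if (p$onset < 0 || p$onset >= duration)
      stop("pulse onset must lie within [0, duration)")
    session_add_pulse(sess, p)
  }
  session_step(sess, round(duration * 1000))
  collect_result(sess)
}

#' @export
print.ctc_result <- function(x, ...) {
  cat("<ctc_result>", nrow(x$spikes), "spikes over", format(x$duration),
      "s;", length(x$pulses_applied), "pulses\n")
  invisible(x)
}

#' Construct an analog trace
#' @param samples numeric samples. @param fs sampling rate (Hz).
#' @param t0 start time (s).
#' @export
analog_trace <- function(samples, fs = 1000, t0 = 0) {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ctc_trace")
}

#' Extract a 1 kHz population analysis signal
#'
#' Rate components are per-ms spike counts of the pool divided by pool size
#' and bin width (Hz). Current components ("current_from:<source>") are the
#' summed synaptic current (A) of that source into the population's
#' excitatory pool, averaged within each 1 ms bin; inhibitory-origin
#' currents are negative-going.
#'
#' @param result \code{ctc_result}.
#' @param population population id.
#' @param component "exc_rate", "inh_rate" or "current_from:<source>" with
#'   source one of the keys in \code{result$signals_1khz[[population]]$currents}
#'   (e.g. "drive", "col_inh", "X_exc").
#' @return \code{\link{analog_trace}} at 1 kHz.
#' @export
extract_population_signal <- function(result, population, component) {
  sig <- result$signals_1khz[[population]]
  if (is.null(sig)) stop("unknown population '", population, "'")
  if (component %in% c("exc_rate", "inh_rate"))
    return(analog_trace(sig[[component]]))
  if (startsWith(component, "current_from:")) {
    key <- sub("^current_from:", "", component)
    cur <- sig$currents[[key]]
    if (is.null(cur))
      stop("no current component '", key, "' recorded for population '",
           population, "'")
    return(analog_trace(cur))
  }
  stop("unknown component '", component, "'")
}

#' Mean firing rates of a simulation
#'
#' @param result \code{ctc_result}.
#' @param skip initial transient to discard (s).
#' @return data.frame with population, pool and mean rate (Hz, spikes per
#'   neuron per second).
#' @export
mean_rates <- function(result, skip = 0.5) {
  span <- result$duration - skip
  stopifnot(span > 0)
  pops <- vapply(result$config$populations, `[[`, "", "id")
  out <- expand.grid(population = pops, pool = c("exc", "inh"),
                     stringsAsFactors = FALSE)
  ns <- vapply(result$config$populations, function(p)
    c(p$n_exc, p$n_inh), numeric(2))
  out$rate <- mapply(function(pop, pool) {
    n <- ns[if (pool == "exc") 1 else 2, match(pop, pops)]
    sum(result$spikes$time >= skip & result$spikes$population == pop &
          result$spikes$pool == pool) / n / span
  }, out$population, out$pool)
  out
}
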