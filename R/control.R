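# Closed-loop controllers.
#
# Sync mode: keep two independent columns phase-locked by pulsing column X
# at the onset phase whose mean PRC shift best cancels the accumulated
# phase difference. Switch mode: hold the XYZ network in a target routing
# state by pulsing a chosen column at the onset phase with the highest
# switch probability. Both fire single 1 ms pulses, edge-triggered on the
# live (AR-forecast) phase, with a refractory period after every pulse.

#' Classify the XYZ routing state
#'
#' State Tr^X when Z is entrained by X: the phase difference between the
#' X_e-origin current into Z_e and the Z_i-origin current lies in
#' (0, 0.5 pi) (a quarter of all phases); Tr^Y symmetrically; anything
#' else is a transition. NA phases give "unknown".
#'
#' Because "phase zero" of a band-passed current signal is defined only up
#' to a waveform-dependent reference, \code{offset} rotates the measured
#' differences into the convention in which the favorable alignment spans
#' (0, 0.5 pi); estimate it once per condition with
#' \code{\link{estimate_state_offset}}.
#'
#' @param phi_zx,phi_zy phase differences Phi_ZX, Phi_ZY (rad).
#' @param offset phase-reference offset added to both differences (rad).
#' @return \code{ctc_state}: list(label, phi_zx, phi_zy) (offset applied).
#' @export
classify_state <- function(phi_zx, phi_zy, offset = 0) {
  phi_zx <- wrap_angle(phi_zx + offset)
  phi_zy <- wrap_angle(phi_zy + offset)
  lab <- if (is.na(phi_zx) || is.na(phi_zy)) "unknown"
  else {
    in_x <- phi_zx > 0 && phi_zx < 0.5 * pi
    in_y <- phi_zy > 0 && phi_zy < 0.5 * pi
    if (in_x && in_y) {     # antiphase violated within tolerance: pick closer
      if (circ_dist(phi_zx, 0.25 * pi) <= circ_dist(phi_zy, 0.25 * pi))
        "TrX" else "TrY"
    } else if (in_x) "TrX" else if (in_y) "TrY" else "transition"
  }
  structure(list(label = lab, phi_zx = phi_zx, phi_zy = phi_zy),
            class = "ctc_state")
}

#' Controller configuration
#'
#' @param mode "sync" or "switch".
#' @param threshold allowed phase-difference excursion before the sync
#'   controller acts (rad; pi/4 = an eighth of a cycle).
#' @param tau_ref refractory period after each pulse (s).
#' @param amplitude pulse amplitude (A). @param pulse_duration (s).
#' @param pulse_target population to pulse.
#' @param target_state "TrX" or "TrY" (switch mode).
#' @param optimal_onset onset phase maximizing the switch probability
#'   (switch mode; from \code{\link{switch_map}}).
#' @param prc \code{ctc_prc} mean PRC of the pulse amplitude in use (sync
#'   mode).
#' @export
controller_config <- function(mode = c("sync", "switch"), threshold = pi / 4,
                              tau_ref = 0.1, amplitude = 1e-9,
                              pulse_duration = 1e-3, pulse_target = "X",
                              target_state = "TrX", optimal_onset = NULL,
                              prc = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < pi, tau_ref > 0)
  structure(list(mode = mode, threshold = threshold, tau_ref = tau_ref,
                 amplitude = amplitude, pulse_duration = pulse_duration,
                 pulse_target = pulse_target, target_state = target_state,
                 optimal_onset = optimal_onset, prc = prc),
            class = "ctc_controller")
}

# edge-triggered phase crossing between consecutive control ticks:
# the wrapped distance to the target onset changes sign from - to +
# without a wrap jump
phase_crossed <- function(phi_prev, phi_now, onset) {
  if (is.na(phi_prev) || is.na(phi_now)) return(FALSE)
  d0 <- wrap_angle(phi_prev - onset)
  d1 <- wrap_angle(phi_now - onset)
  d0 < 0 && d1 >= 0 && abs(d0) < 1 && abs(d1) < 1
}

#' Sync-controller pulse decision
#'
#' Fire when (1) the refractory period has elapsed, (2) |Phi_XY| exceeds
#' the threshold, and (3) the live phase of X crosses the onset phase whose
#' tabulated mean PRC shift is circularly closest to the required
#' correction -Phi_XY (ties broken toward the smaller required shift). If
#' the PRC has no defined bins the controller degrades to pulsing at any
#' phase whenever outside the target window (fallback flagged in the
#' result).
#'
#' @param phi_x,phi_y live phases (rad).
#' @param config \code{\link{controller_config}} with \code{prc}.
#' @param t current time (s). @param last_pulse time of the previous pulse
#'   (s, -Inf if none). @param phi_x_prev phase of X at the previous tick.
#' @return list(fire, onset_phase, required_shift, fallback).
#' @export
sync_controller <- function(phi_x, phi_y, config, t, last_pulse = -Inf,
                            phi_x_prev = NA) {
  out <- list(fire = FALSE, onset_phase = NA_real_,
              required_shift = NA_real_, fallback = FALSE)
  if (is.na(phi_x) || is.na(phi_y)) return(out)
  if (t - last_pulse < config$tau_ref) return(out)
  dphi <- wrap_angle(phi_x - phi_y)
  if (abs(dphi) <= config$threshold) return(out)
  required <- wrap_angle(-dphi)
  out$required_shift <- required
  prc <- config$prc
  ok <- which(prc$defined)
  if (!length(ok)) {                     # high-noise fallback: just push
    out$fallback <- TRUE
    out$fire <- TRUE
    out$onset_phase <- phi_x
    return(out)
  }
  err <- circ_dist(prc$mean_shift[ok], required)
  best <- ok[order(err, abs(prc$mean_shift[ok]))][1]
  out$onset_phase <- prc$phi_grid[best]
  out$fire <- phase_crossed(phi_x_prev, phi_x, out$onset_phase)
  out
}

#' Switch-controller pulse decision
#'
#' Fire iff the refractory period has elapsed, the classified state
#' differs from the target (and is not unknown), and the live phase of the
#' pulsed population crosses the optimal onset phase.
#'
#' @param state \code{ctc_state}. @param phi live phase of the pulsed
#'   population. @param config \code{\link{controller_config}} with
#'   \code{optimal_onset}. @param t time (s). @param last_pulse previous
#'   pulse time. @param phi_prev phase at the previous tick.
#' @return TRUE to fire.
#' @export
switch_controller <- function(state, phi, config, t, last_pulse = -Inf,
                              phi_prev = NA) {
  if (t - last_pulse < config$tau_ref) return(FALSE)
  if (state$label %in% c("unknown", config$target_state)) return(FALSE)
  phase_crossed(phi_prev, phi, config$optimal_onset)
}

# live phase of a population signal from a running session; responses to
# pulses fired earlier are zeroed like offline artifacts
live_phase <- function(session, pop, component, model, window = 0.384,
                       last_pulse = -Inf) {
  n <- round(window * 1000)
  x <- session_tail(session, pop, component, n)
  if (length(x) <= model$order + 10) return(NA_real_)
  t_now <- session_time(session)
  arts <- list()
  i0 <- length(x) - round((t_now - last_pulse) * 1000)
  if (is.finite(last_pulse) && i0 + 11 >= 1)
    arts <- list(c(i0, i0 + 11))
  tryCatch(realtime_phase(model, analog_trace(boxcar3(x)), model$band,
                          artifacts = arts),
           error = function(e) NA_real_)
}

#' Run the closed-loop synchronization task
#'
#' Two independent calibrated columns X and Y run side by side; the
#' controller tracks both phases in real time (1 ms control ticks) and
#' pulses X per \code{\link{sync_controller}}.
#'
#' @param config calibrated \code{\link{build_column_pair}} config.
#' @param controller \code{\link{controller_config}} (mode "sync").
#' @param duration run length (s). @param seed realization seed.
#' @param warmup history accumulated before control starts (s).
#' @param models list(X=, Y=) of \code{ctc_ar} models with bands (from an
#'   unperturbed training run); NULL fits them on a fresh 10 s run.
#' @return \code{ctc_control_log}: list(pulses, state_trace, time_in_target,
#'   result, fallback_used).
#' @export
run_sync_control <- function(config, controller, duration = 10, seed = 1,
                             warmup = 0.5, models = NULL) {
  stopifnot(controller$mode == "sync")
  if (is.null(models)) {
    train <- simulate_network(config, 10, seed = seed * 13 + 1)
    models <- lapply(c(X = "X", Y = "Y"), function(id) {
      s <- analysis_signal(train, id)
      fit_ar(s, band = estimate_gamma_band(s))
    })
  }
  sess <- sim_session(config, duration, seed = seed)
  session_step(sess, round(warmup * 1000))
  n_ticks <- round((duration - warmup) * 1000)
  last_pulse <- -Inf
  phi_x_prev <- NA
  fallback_used <- FALSE
  st <- data.frame(t = numeric(n_ticks), phi_xy = NA_real_, fired = FALSE)
  pulses <- list()
  for (k in seq_len(n_ticks)) {
    t <- session_time(sess)
    phi_x <- live_phase(sess, "X", "exc_rate", models$X,
                        last_pulse = last_pulse)
    phi_y <- live_phase(sess, "Y", "exc_rate", models$Y,
                        last_pulse = last_pulse)
    dec <- sync_controller(phi_x, phi_y, controller, t, last_pulse,
                           phi_x_prev)
    st$t[k] <- t
    st$phi_xy[k] <- if (is.na(phi_x) || is.na(phi_y)) NA
                    else wrap_angle(phi_x - phi_y)
    if (dec$fire) {
      p <- stimulation_pulse(controller$pulse_target, controller$amplitude,
                             t, controller$pulse_duration)
      session_add_pulse(sess, p)
      last_pulse <- t
      fallback_used <- fallback_used || dec$fallback
      st$fired[k] <- TRUE
      pulses[[length(pulses) + 1]] <- data.frame(
        time = t, onset_phase = phi_x, required_shift = dec$required_shift)
    }
    phi_x_prev <- phi_x
    session_step(sess, 1)
  }
  res <- collect_result(sess)
  ok <- !is.na(st$phi_xy)
  structure(list(pulses = do.call(rbind, pulses), state_trace = st,
                 time_in_target = mean(abs(st$phi_xy[ok]) < controller$threshold),
                 result = res, fallback_used = fallback_used,
                 controller = controller), class = "ctc_control_log")
}

#' @export
print.ctc_control_log <- function(x, ...) {
  np <- if (is.null(x$pulses)) 0 else nrow(x$pulses)
  cat("<ctc_control_log>", np, "pulses; time in target",
      signif(x$time_in_target, 3), "\n")
  invisible(x)
}

# AR models for the three Z-input currents and the pulsed population,
# plus the state phase-reference offset, from one unperturbed training run
switch_models <- function(config, seed) {
  train <- simulate_network(config, 10, seed = seed * 13 + 1)
  keys <- c(xe = "X_exc", ye = "Y_exc", zi = "Z_inh")
  mods <- lapply(keys, function(key) {
    s <- analysis_signal(train, "Z", paste0("current_from:", key))
    fit_ar(s, band = estimate_gamma_band(s))
  })
  pops <- c("X", "Y", "Z")
  rate_mods <- lapply(stats::setNames(pops, pops), function(id) {
    s <- analysis_signal(train, id)
    fit_ar(s, band = estimate_gamma_band(s))
  })
  list(currents = mods, rates = rate_mods,
       offset = estimate_state_offset(train))
}

#' Run the closed-loop routing-state controller
#'
#' The XYZ network runs while the controller classifies the routing state
#' every millisecond from the real-time phases of the X_e-, Y_e- and
#' Z_i-origin currents into Z_e, and pulses the configured column at its
#' optimal onset phase whenever the network is in the wrong state (per
#' \code{\link{switch_controller}}).
#'
#' @param config calibrated XYZ config.
#' @param controller \code{\link{controller_config}} (mode "switch").
#' @param duration,seed,warmup as in \code{\link{run_sync_control}}.
#' @param models output of an internal training step; NULL fits on a fresh
#'   10 s run.
#' @return \code{ctc_control_log} with a per-tick state trace (label,
#'   Phi_ZX, Phi_ZY, fired).
#' @export
run_switch_control <- function(config, controller, duration = 10, seed = 1,
                               warmup = 0.5, models = NULL) {
  stopifnot(controller$mode == "switch")
  models <- models %||% switch_models(config, seed)
  sess <- sim_session(config, duration, seed = seed)
  session_step(sess, round(warmup * 1000))
  n_ticks <- round((duration - warmup) * 1000)
  last_pulse <- -Inf
  phi_prev <- NA
  st <- data.frame(t = numeric(n_ticks), label = "unknown",
                   phi_zx = NA_real_, phi_zy = NA_real_, fired = FALSE)
  pulses <- list()
  pt <- controller$pulse_target
  for (k in seq_len(n_ticks)) {
    t <- session_time(sess)
    phx <- live_phase(sess, "Z", "X_exc", models$currents$xe,
                      last_pulse = last_pulse)
    phy <- live_phase(sess, "Z", "Y_exc", models$currents$ye,
                      last_pulse = last_pulse)
    phz <- live_phase(sess, "Z", "Z_inh", models$currents$zi,
                      last_pulse = last_pulse)
    state <- classify_state(wrap_angle(phx - phz), wrap_angle(phy - phz),
                            offset = models$offset %||% 0)
    phi <- live_phase(sess, pt, "exc_rate", models$rates[[pt]],
                      last_pulse = last_pulse)
    fire <- switch_controller(state, phi, controller, t, last_pulse,
                              phi_prev)
    st$t[k] <- t
    st$label[k] <- state$label
    st$phi_zx[k] <- state$phi_zx
    st$phi_zy[k] <- state$phi_zy
    if (fire) {
      session_add_pulse(sess, stimulation_pulse(pt, controller$amplitude, t,
                                                controller$pulse_duration))
      last_pulse <- t
      st$fired[k] <- TRUE
      pulses[[length(pulses) + 1]] <- data.frame(time = t, onset_phase = phi)
    }
    phi_prev <- phi
    session_step(sess, 1)
  }
  res <- collect_result(sess)
  structure(list(pulses = do.call(rbind, pulses), state_trace = st,
                 time_in_target = mean(st$label == controller$target_state),
                 result = res, controller = controller),
            class = "ctc_control_log")
}

#' Offline routing-state trace of an XYZ simulation
#'
#' Offline (Hilbert) phases of the three Z-input currents, their
#' differences Phi_ZX and Phi_ZY, and the per-ms state label.
#'
#' @param result XYZ \code{ctc_result}.
#' @param offset phase-reference offset (rad); NULL estimates it from this
#'   result via \code{\link{estimate_state_offset}}.
#' @return data.frame: t, phi_zx, phi_zy (offset applied), label; the
#'   offset used is attached as attribute "offset".
#' @export
state_trace_offline <- function(result, offset = NULL) {
  sig <- lapply(c(xe = "X_exc", ye = "Y_exc", zi = "Z_inh"), function(key)
    analysis_signal(result, "Z", paste0("current_from:", key)))
  ph <- lapply(sig, function(s) offline_phase(s, estimate_gamma_band(s)))
  n <- length(ph$xe$phase)
  phi_zx <- wrap_angle(ph$xe$phase - ph$zi$phase)
  phi_zy <- wrap_angle(ph$ye$phase - ph$zi$phase)
  valid <- ph$xe$valid & ph$ye$valid & ph$zi$valid
  phi_zx[!valid] <- NA
  phi_zy[!valid] <- NA
  if (is.null(offset))
    offset <- estimate_state_offset_raw(result, phi_zx, valid)
  phi_zx <- wrap_angle(phi_zx + offset)
  phi_zy <- wrap_angle(phi_zy + offset)
  lab <- vapply(seq_len(n), function(i)
    classify_state(phi_zx[i], phi_zy[i])$label, character(1))
  structure(data.frame(t = (seq_len(n) - 1) / 1000, phi_zx = phi_zx,
                       phi_zy = phi_zy, label = lab), offset = offset)
}

# offset from already-computed raw phase differences
estimate_state_offset_raw <- function(result, phi_zx_raw, valid) {
  ok <- valid & !is.na(phi_zx_raw)
  # the two attractors lie pi apart: angle doubling collapses them onto one
  # axis whose direction is the mode location (up to the pi ambiguity)
  axis <- Arg(mean(exp(2i * phi_zx_raw[ok]))) / 2
  cands <- c(axis, wrap_angle(axis + pi))
  # the X-favorable mode is the one where Z spiking tracks the X_e current
  zr <- analysis_signal(result, "Z")$samples
  zx <- analysis_signal(result, "Z", "current_from:X_exc")$samples
  score <- vapply(cands, function(cand) {
    sel <- ok & abs(wrap_angle(phi_zx_raw - cand)) < pi / 4
    if (sum(sel) < 100) return(-Inf)
    stats::cor(zr[sel], zx[sel])
  }, numeric(1))
  wrap_angle(0.25 * pi - cands[which.max(score)])
}

#' Estimate the routing-state phase-reference offset
#'
#' Locates the attractors of the passive phase-difference distribution
#' (angle doubling collapses the two pi-separated modes onto one axis),
#' identifies the X-favorable mode as the one in which Z spiking
#' correlates with the X_e-origin current, and returns the rotation that
#' centers that mode at 0.25 pi (the middle of the Tr^X window).
#'
#' @param result passive XYZ \code{ctc_result} (>= a few seconds).
#' @return offset (rad) for \code{\link{classify_state}} /
#'   \code{\link{state_trace_offline}}.
#' @export
estimate_state_offset <- function(result) {
  sig <- lapply(c(xe = "X_exc", zi = "Z_inh"), function(key)
    analysis_signal(result, "Z", paste0("current_from:", key)))
  ph <- lapply(sig, function(s) offline_phase(s, estimate_gamma_band(s)))
  phi_zx <- wrap_angle(ph$xe$phase - ph$zi$phase)
  estimate_state_offset_raw(result, phi_zx, ph$xe$valid & ph$zi$valid)
}

#' Evaluate controller performance against a passive baseline
#'
#' @param control_logs list of \code{ctc_control_log} (equal durations).
#' @param passive_results list of passive XYZ \code{ctc_result}s of the
#'   same duration.
#' @param target_state "TrX" or "TrY".
#' @return list: \code{time_in_target} (controlled), \code{passive_baseline}
#'   (fraction of time passively in the target state),
#'   \code{routing_difference} (mean over controlled runs of
#'   SC(S_X in Z) - SC(S_Y in Z)), \code{routing_p} (two-sided paired-free
#'   t-test of the per-run differences against zero), \code{per_run}.
#' @export
evaluate_performance <- function(control_logs, passive_results,
                                 target_state = "TrX") {
  dur <- control_logs[[1]]$result$duration
  for (r in passive_results)
    if (abs(r$duration - dur) > 1e-9)
      stop("pulsed and passive runs must have equal durations (sample-size bias)")
  tit <- vapply(control_logs, `[[`, numeric(1), "time_in_target")
  base <- vapply(passive_results, function(r) {
    stt <- state_trace_offline(r)
    mean(stt$label == target_state, na.rm = TRUE)
  }, numeric(1))
  per_run <- t(vapply(control_logs, function(lg) {
    z <- analysis_signal(lg$result, "Z")
    scx <- sc_score(z, lg$result$flickers$X)
    scy <- sc_score(z, lg$result$flickers$Y)
    c(sc_x = scx, sc_y = scy, diff = scx - scy)
  }, numeric(3)))
  pval <- if (nrow(per_run) >= 2 && stats::sd(per_run[, "diff"]) > 0)
    stats::t.test(per_run[, "diff"])$p.value else NA_real_
  list(time_in_target = mean(tit), passive_baseline = mean(base),
       routing_difference = mean(per_run[, "diff"]), routing_p = pval,
       per_run = per_run, per_run_time_in_target = tit,
       per_run_baseline = base)
}
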