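# Experiment drivers: reproduce the study's figure-level analyses at a
# configurable scale. "desk" scale uses reduced run counts and durations
# (documented per experiment); "full" matches the original protocol sizes.
# Every bundle records its name, scale, seed and a per-table manifest, and
# identical (spec, seed) pairs reproduce identical numeric tables.

experiment_names <- c("single_column_noise_sweep", "phase_error", "prc_grid",
                      "sync_task", "xyz_characterization", "switch_maps",
                      "time_in_state", "routing")

desk_noise_grid <- c(0, 0.075e-9, 0.15e-9)
full_noise_grid <- c(0, 0.05e-9, 0.075e-9, 0.1e-9, 0.15e-9, 0.175e-9)

#' Spectral peak frequency of a trace
#'
#' Argmax of the time-averaged Morlet power spectrum within \code{search}.
#'
#' @param trace \code{analog_trace} or numeric (1 kHz).
#' @param search frequency range (Hz).
#' @return peak frequency (Hz).
#' @export
spectral_peak <- function(trace, search = c(20, 120)) {
  estimate_gamma_band(as_trace(trace), search = search)$f_peak
}

#' Run a named experiment
#'
#' @param name one of "single_column_noise_sweep", "phase_error",
#'   "prc_grid", "sync_task", "xyz_characterization", "switch_maps",
#'   "time_in_state", "routing".
#' @param scale "desk" (reduced run counts, default) or "full".
#' @param seed master seed.
#' @param out_dir optional directory; tables are written as CSV plus a JSON
#'   manifest.
#' @param overrides named list overriding experiment parameters (noise
#'   grid, amplitudes, run counts, durations).
#' @return \code{ctc_bundle}: list(name, scale, seed, tables, meta).
#' @export
run_experiment <- function(name, scale = c("desk", "full"), seed = 1,
                           out_dir = NULL, overrides = list()) {
  name <- match.arg(name, experiment_names)
  scale <- match.arg(scale)
  fn <- get(paste0("exp_", name), mode = "function")
  tables <- fn(scale, seed, overrides)
  bundle <- structure(list(name = name, scale = scale, seed = seed,
                           tables = tables,
                           meta = list(timestamp = format(Sys.time()),
                                       tables = names(tables))),
                      class = "ctc_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.ctc_bundle <- function(x, ...) {
  cat("<ctc_bundle>", x$name, "| scale:", x$scale, "| seed:", x$seed,
      "| tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Write an experiment bundle to disk
#' @param bundle \code{ctc_bundle}. @param out_dir directory (created).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    tb <- bundle$tables[[nm]]
    if (is.data.frame(tb))
      utils::write.csv(tb, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(
    list(name = bundle$name, scale = bundle$scale, seed = bundle$seed,
         meta = bundle$meta),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(bundle)
}

#' Summarize an experiment bundle
#' @param bundle \code{ctc_bundle}.
#' @return data.frame of headline quantities (one row per measure).
#' @export
summarize_bundle <- function(bundle) {
  rows <- list()
  for (nm in names(bundle$tables)) {
    tb <- bundle$tables[[nm]]
    if (!is.data.frame(tb)) next
    num <- vapply(tb, is.numeric, logical(1))
    for (cn in names(tb)[num])
      rows[[paste(nm, cn, sep = ".")]] <-
        data.frame(experiment = bundle$name, table = nm, measure = cn,
                   mean = mean(tb[[cn]], na.rm = TRUE),
                   min = suppressWarnings(min(tb[[cn]], na.rm = TRUE)),
                   max = suppressWarnings(max(tb[[cn]], na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- experiment implementations --------------------------------------------

exp_single_column_noise_sweep <- function(scale, seed, ov) {
  grid <- ov$noise_grid %||% if (scale == "desk") desk_noise_grid
                             else full_noise_grid
  dur <- ov$duration %||% 10
  nsur <- ov$n_surrogates %||% 100
  rows <- lapply(grid, function(nz) {
    cal <- calibrate_drives(build_single_column(noise_level = nz, seed = seed),
                            seed = seed)
    res <- simulate_network(cal$config, dur, seed = seed + 17)
    r <- mean_rates(res)
    sig <- analysis_signal(res, "col")
    sc <- sc_score(sig, res$flickers$col)
    ch <- chance_level(sig, function(i)
      generate_flicker(dur, seed = seed * 1000 + i), n_surrogates = nsur)
    data.frame(noise = nz, rate_exc = pool_rate(r, "col", "exc"),
               rate_inh = pool_rate(r, "col", "inh"),
               peak_freq = spectral_peak(sig), sc = sc,
               chance_95 = as.numeric(ch), converged = cal$converged)
  })
  list(noise_sweep = do.call(rbind, rows))
}

exp_phase_error <- function(scale, seed, ov) {
  grid <- ov$noise_grid %||% if (scale == "desk") desk_noise_grid
                             else full_noise_grid
  dur <- ov$duration %||% 10
  n_probe <- ov$n_probe %||% 40
  rows <- lapply(grid, function(nz) {
    cfg <- build_single_column(noise_level = nz, seed = seed)
    train <- simulate_network(cfg, 10, seed = seed + 5)
    sig0 <- analysis_signal(train, "col")
    band <- estimate_gamma_band(sig0)
    ar <- fit_ar(sig0, band = band)
    res <- simulate_network(cfg, dur, seed = seed + 23)
    sig <- analysis_signal(res, "col")
    off <- offline_phase(sig, band)
    ts <- seq(1, dur - 0.5, length.out = n_probe)
    diffs <- vapply(ts, function(t) {
      i <- round(t * 1000)
      rt <- tryCatch(realtime_phase(ar, analog_trace(sig$samples[seq_len(i)]),
                                    band), error = function(e) NA_real_)
      if (is.na(rt) || !off$valid[i]) NA_real_
      else wrap_angle(rt - off$phase[i])
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    cs <- circular_stats(diffs)
    data.frame(noise = nz, n = length(diffs), mean_diff = cs$mean,
               resultant = cs$resultant,
               circ_sd = sqrt(-2 * log(max(cs$resultant, 1e-12))))
  })
  list(phase_error = do.call(rbind, rows))
}

exp_prc_grid <- function(scale, seed, ov) {
  grid <- ov$noise_grid %||% if (scale == "desk") c(0.075e-9)
                             else desk_noise_grid
  amps <- ov$amplitudes %||%
    (if (scale == "desk") c(-1, 1, 2, 4) * 1e-9
     else c(-4, -2, -1, -0.5, -0.25, 0.25, 0.5, 1, 2, 4) * 1e-9)
  n_runs <- ov$n_runs %||% if (scale == "desk") 300 else 2500
  tau_grid <- ov$tau_grid %||% seq(0, 0.1, by = 5e-3)
  tabs <- list()
  for (nz in grid) {
    cal <- calibrate_drives(build_single_column(noise_level = nz, seed = seed),
                            seed = seed)
    batch <- run_pulse_experiment(cal$config, amps, n_runs = n_runs,
                                  seed = seed)
    for (a in setdiff(batch$amplitudes, 0)) {
      pb <- prc_by_tau(batch, a, tau_grid)
      st <- settle_time(pb$prcs)
      tau_read <- 0.1
      prc <- pb$prcs[[which.min(abs(tau_grid - tau_read))]]
      tabs[[sprintf("prc_n%g_a%g", nz * 1e9, a * 1e9)]] <-
        data.frame(noise = nz, amplitude = a, phi = prc$phi_grid,
                   mean_shift = prc$mean_shift, q25 = prc$q25,
                   q75 = prc$q75, resultant = prc$resultant, n = prc$n,
                   defined = prc$defined, settle_tau = st$tau %||% NA)
    }
  }
  tabs
}

exp_sync_task <- function(scale, seed, ov) {
  nz <- ov$noise %||% 0.075e-9
  amps <- ov$amplitudes %||% if (scale == "desk") c(-1, 1) * 1e-9
                             else c(-4, -1, 1, 4) * 1e-9
  dur <- ov$duration %||% if (scale == "desk") 10 else 30
  prc_runs <- ov$prc_runs %||% if (scale == "desk") 150 else 2500
  cal <- calibrate_drives(build_column_pair(noise_level = nz, seed = seed),
                          seed = seed)
  cfg <- cal$config
  # PRC of column X inside the pair, for the controller inversion
  rows <- list(); dist_tab <- list()
  for (a in amps) {
    batch <- run_pulse_experiment(cfg, a, n_runs = prc_runs,
                                  pulse_target = "X", seed = seed + 31,
                                  track = list(X = "exc_rate"))
    prc <- estimate_prc_density(
      pair_and_shift(batch_subset(batch, a), batch_subset(batch, 0),
                     tau_grid = 0.1), 0.1)
    ctl <- controller_config("sync", amplitude = a, prc = prc)
    log <- run_sync_control(cfg, ctl, duration = dur, seed = seed + 7)
    sc <- sc_score(analysis_signal(log$result, "X"), log$result$flickers$X)
    rows[[length(rows) + 1]] <- data.frame(
      amplitude = a, time_in_target = log$time_in_target,
      n_pulses = if (is.null(log$pulses)) 0L else nrow(log$pulses),
      sc = sc)
    dist_tab[[length(dist_tab) + 1]] <-
      data.frame(amplitude = a, phi_xy = log$state_trace$phi_xy)
  }
  # passive baseline
  pas <- simulate_network(cfg, dur, seed = seed + 7)
  sigx <- analysis_signal(pas, "X"); sigy <- analysis_signal(pas, "Y")
  phx <- offline_phase(sigx, estimate_gamma_band(sigx))
  phy <- offline_phase(sigy, estimate_gamma_band(sigy))
  ok <- phx$valid & phy$valid
  pass_phi <- wrap_angle(phx$phase - phy$phase)[ok]
  list(sync = do.call(rbind, rows),
       phi_xy = do.call(rbind, dist_tab),
       passive = data.frame(
         time_in_target = mean(abs(pass_phi) < pi / 4),
         sc = sc_score(sigx, pas$flickers$X)))
}

#' State-conditioned signal-content scores of an XYZ run
#'
#' SC of each input flicker (S_X, S_Y) in the Z output, overall and
#' restricted to the periods the network spends in each routing state
#' (out-of-state samples of both input and output are zeroed under a
#' common mask, so scores within a run share the same effective duration
#' and are comparable).
#'
#' @param result passive XYZ \code{ctc_result}.
#' @param stt optional precomputed \code{\link{state_trace_offline}}.
#' @param min_ms minimum number of in-state samples to score a state.
#' @return data.frame with columns state ("all", "TrX", "TrY"), sc_x, sc_y.
#' @export
routing_scores <- function(result, stt = NULL, min_ms = 1500) {
  stt <- stt %||% state_trace_offline(result)
  dur <- result$duration
  z <- analysis_signal(result, "Z")
  fx <- flicker_trace(result$flickers$X, 1000, dur)
  fy <- flicker_trace(result$flickers$Y, 1000, dur)
  one <- function(mask) {
    if (sum(mask) < min_ms) return(c(NA_real_, NA_real_))
    zz <- z$samples; zz[!mask] <- mean(zz[mask])
    fxm <- fx; fxm[!mask] <- 0
    fym <- fy; fym[!mask] <- 0
    c(sc_score(analog_trace(zz), fxm), sc_score(analog_trace(zz), fym))
  }
  rows <- rbind(all = one(rep(TRUE, length(z$samples))),
                TrX = one(stt$label == "TrX"),
                TrY = one(stt$label == "TrY"))
  data.frame(state = rownames(rows), sc_x = rows[, 1], sc_y = rows[, 2],
             row.names = NULL)
}

exp_xyz_characterization <- function(scale, seed, ov) {
  grid <- ov$noise_grid %||% if (scale == "desk") c(0.075e-9)
                             else desk_noise_grid
  dur <- ov$duration %||% 10
  n_runs <- ov$n_runs %||% if (scale == "desk") 3 else 10
  rows <- list()
  for (nz in grid) {
    net <- calibrated_network("xyz", noise_level = nz, seed = seed)
    for (r in seq_len(n_runs)) {
      res <- simulate_network(net$config, dur, seed = seed + 100 + r)
      stt <- state_trace_offline(res)
      rs <- routing_scores(res, stt)
      rows[[length(rows) + 1]] <- data.frame(
        noise = nz, run = r,
        frac_trx = mean(stt$label == "TrX"),
        frac_try = mean(stt$label == "TrY"),
        sc_x_in_z = rs$sc_x[rs$state == "all"],
        sc_y_in_z = rs$sc_y[rs$state == "all"],
        sc_x_in_z_trx = rs$sc_x[rs$state == "TrX"],
        sc_y_in_z_trx = rs$sc_y[rs$state == "TrX"],
        sc_x_in_z_try = rs$sc_x[rs$state == "TrY"],
        sc_y_in_z_try = rs$sc_y[rs$state == "TrY"],
        sc_x_in_x = sc_score(analysis_signal(res, "X"), res$flickers$X),
        sc_y_in_x = sc_score(analysis_signal(res, "X"), res$flickers$Y))
    }
  }
  list(xyz = do.call(rbind, rows))
}

exp_switch_maps <- function(scale, seed, ov) {
  nz <- ov$noise %||% 0.075e-9
  amps <- ov$amplitudes %||% if (scale == "desk") c(-1, 1, 4) * 1e-9
                             else c(-4, -2, -1, 1, 2, 4) * 1e-9
  targets <- ov$targets %||% c("X", "Y", "Z")
  n_runs <- ov$n_runs %||% if (scale == "desk") 300 else 2500
  net <- calibrated_network("xyz", noise_level = nz, seed = seed)
  tabs <- list()
  for (tg in targets) {
    batch <- run_pulse_experiment(net$config, amps, n_runs = n_runs,
                                  pulse_target = tg, seed = seed + 11)
    for (a in setdiff(batch$amplitudes, 0)) {
      sm <- switch_map_from_batch(batch, a, tau = 0.1)
      tabs[[sprintf("switch_%s_a%g", tg, a * 1e9)]] <-
        data.frame(target = tg, amplitude = a, phi = sm$phi_grid,
                   p_sw = sm$p_sw, delta_p_sw = sm$delta_p_sw,
                   p_passive = sm$p_passive, n = sm$n)
    }
  }
  tabs
}

exp_time_in_state <- function(scale, seed, ov) {
  nz <- ov$noise %||% 0.075e-9
  amp <- ov$amplitude %||% 1e-9
  tg <- ov$pulse_target %||% "X"
  dur <- ov$duration %||% 10
  n_runs <- ov$n_runs %||% if (scale == "desk") 2 else 10
  sw_runs <- ov$sw_runs %||% if (scale == "desk") 200 else 2500
  net <- calibrated_network("xyz", noise_level = nz, seed = seed)
  models <- switch_models(net$config, seed)
  # passive occupancy (same durations)
  passive <- lapply(seq_len(n_runs), function(r)
    simulate_network(net$config, dur, seed = seed + 900 + r))
  base_tab <- lapply(passive, function(res) {
    stt <- state_trace_offline(res, offset = models$offset)
    c(trx = mean(stt$label == "TrX"), try = mean(stt$label == "TrY"))
  })
  base <- colMeans(do.call(rbind, base_tab))
  target_state <- ov$target_state %||% if (base[["trx"]] <= base[["try"]])
    "TrX" else "TrY"
  batch <- run_pulse_experiment(net$config, amp, n_runs = sw_runs,
                                pulse_target = tg, seed = seed + 11)
  sm <- switch_map_from_batch(batch, amp, tau = 0.1,
                              from_state = other_state(target_state),
                              offset = models$offset)
  opt <- sm$phi_grid[which.max(sm$delta_p_sw)]
  ctl <- controller_config("switch", amplitude = amp, pulse_target = tg,
                           target_state = target_state, optimal_onset = opt)
  logs <- lapply(seq_len(n_runs), function(r)
    run_switch_control(net$config, ctl, duration = dur,
                       seed = seed + 900 + r, models = models))
  perf <- evaluate_performance(logs, passive, target_state)
  list(time_in_state = data.frame(
    noise = nz, amplitude = amp, target = tg, target_state = target_state,
    optimal_onset = opt, time_in_target = perf$time_in_target,
    passive_baseline = perf$passive_baseline,
    delta = perf$time_in_target - perf$passive_baseline))
}

exp_routing <- function(scale, seed, ov) {
  nz <- ov$noise %||% 0.075e-9
  amp <- ov$amplitude %||% 1e-9
  dur <- ov$duration %||% 10
  n_runs <- ov$n_runs %||% if (scale == "desk") 20 else 100
  tis <- exp_time_in_state(scale, seed,
                           utils::modifyList(ov, list(n_runs = max(2, n_runs %/% 10))))
  list(routing = tis$time_in_state)
}

other_state <- function(s) if (s == "TrX") "TrY" else "TrX"

#' Switch map of the routing-state difference from an XYZ PRC batch
#'
#' Pairs pulsed and control trials (matching both onset phase and network
#' state), computes shifts of the relevant state phase difference, and
#' reduces them to a switch-probability map versus pulse onset phase.
#'
#' @param batch XYZ \code{ctc_prc_batch}.
#' @param amplitude pulsed amplitude (A).
#' @param tau readout delay (s).
#' @param from_state restrict to trials starting in this state ("TrY" for
#'   Tr^Y -> Tr^X switches); NULL uses all trials.
#' @param offset state phase-reference offset (rad).
#' @param n_bins onset-phase bins.
#' @return \code{ctc_switchmap}.
#' @export
switch_map_from_batch <- function(batch, amplitude, tau = 0.1,
                                  from_state = NULL, offset = 0,
                                  n_bins = 12) {
  pulsed <- batch_subset(batch, amplitude)
  control <- batch_subset(batch, 0)
  if (!is.null(from_state)) {
    keep <- function(tr) {
      s <- tr$state_at_onset
      !any(is.na(s)) &&
        classify_state(s[["phi_zx"]], s[["phi_zy"]], offset)$label == from_state
    }
    pulsed <- Filter(keep, pulsed)
    control <- Filter(keep, control)
  }
  if (length(pulsed) < 10 || length(control) < 10)
    stop("too few trials in the requested starting state")
  # state phase difference Phi_ZX tracked through the Z-input currents
  sh <- pair_and_shift(pulsed, control, tau_grid = tau, signal = "state_zx")
  passive <- pair_and_shift(control[seq(1, length(control), 2)],
                            control[seq(2, length(control), 2)],
                            tau_grid = tau, signal = "state_zx")
  switch_map(sh, passive, tau, n_bins = n_bins)
}
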