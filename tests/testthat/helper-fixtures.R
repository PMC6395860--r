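# Shared, lazily computed fixtures. Heavy simulation products (calibrated
# configs, training runs, PRC batches) are built once per test session and
# reused across files; everything derives from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# calibrated single column at the intermediate noise level
col_config <- function() fixture("col_config", {
  calibrate_drives(build_single_column(noise_level = 0.075e-9, seed = 2),
                   seed = 11)$config
})

# one 10 s unperturbed run of it
col_run <- function() fixture("col_run", simulate_network(col_config(), 10,
                                                          seed = 42))

col_band <- function() fixture("col_band",
  estimate_gamma_band(analysis_signal(col_run(), "col")))

col_ar <- function() fixture("col_ar",
  fit_ar(analysis_signal(col_run(), "col"), band = col_band()))

# single-column PRC batch across the pulse-amplitude ladder (shared by the
# settle-time, reset-shape and dose-response checks)
col_prc_batch <- function() fixture("col_prc_batch", {
  run_pulse_experiment(col_config(),
                       amplitudes = c(-4, -1, 0.25, 0.5, 1, 2, 4) * 1e-9,
                       n_runs = 80, seed = 7)
})

# calibrated XYZ network at the intermediate noise level
xyz_config <- function() fixture("xyz_config", {
  calibrated_network("xyz", noise_level = 0.075e-9, seed = 3)$config
})

# passive XYZ runs (8 x 8 s) with state traces and routing scores
xyz_passive <- function() fixture("xyz_passive", {
  lapply(1:8, function(r) {
    res <- simulate_network(xyz_config(), 8, seed = 300 + r)
    stt <- state_trace_offline(res)
    list(result = res, stt = stt, scores = routing_scores(res, stt))
  })
})

# synthetic phase-trace trial for PRC pairing tests: phase advances at
# `freq` Hz from `phi0` at t = 0; after `t_reset` (if finite) it restarts
# from phase `reset_to`
synth_trial <- function(phi0, amplitude = 1e-9, onset_time = 0.5,
                        freq = 60, duration = 1, t_reset = Inf,
                        reset_to = 0) {
  n <- duration * 1000
  tt <- (seq_len(n) - 1) / 1000
  ph <- wrap_angle(phi0 + 2 * pi * freq * tt)
  if (is.finite(t_reset)) {
    post <- tt >= t_reset
    ph[post] <- wrap_angle(reset_to + 2 * pi * freq * (tt[post] - t_reset))
  }
  phase <- structure(list(phase = ph, fs = 1000,
                          valid = rep(TRUE, n), t0 = 0),
                     class = "ctc_phase")
  list(amplitude = amplitude, onset_time = onset_time,
       onset_phase = wrap_angle(phi0 + 2 * pi * freq * onset_time),
       state_at_onset = NULL, phases = list(col = phase), seed = 0)
}

# calibrated independent column pair (synchronization task)
sync_pair_config <- function() fixture("sync_pair_config", {
  calibrate_drives(build_column_pair(noise_level = 0.075e-9, seed = 4),
                   seed = 11)$config
})

# AR models/bands for both columns of the pair, from one training run
sync_models <- function() fixture("sync_models", {
  train <- simulate_network(sync_pair_config(), 10, seed = 61)
  lapply(c(X = "X", Y = "Y"), function(id) {
    s <- analysis_signal(train, id)
    fit_ar(s, band = estimate_gamma_band(s))
  })
})

xyz_models <- function() fixture("xyz_models",
  ctcstim:::switch_models(xyz_config(), seed = 5))

# favorable switch-control condition: intermediate noise, moderate pulse
# into X, aiming at the passively less-occupied state
favorable_switch_run <- function() fixture("favorable_switch_run", {
  occ <- vapply(xyz_passive(), function(run)
    c(trx = mean(run$stt$label == "TrX"),
      try = mean(run$stt$label == "TrY")), numeric(2))
  target <- if (mean(occ["trx", ]) <= mean(occ["try", ])) "TrX" else "TrY"
  baseline <- mean(occ[if (target == "TrX") "trx" else "try", ])
  models <- xyz_models()
  batch <- run_pulse_experiment(xyz_config(), 1e-9, n_runs = 30,
                                pulse_target = "X", seed = 21)
  sm <- suppressWarnings(switch_map_from_batch(
    batch, 1e-9, tau = 0.1,
    from_state = if (target == "TrX") "TrY" else "TrX",
    offset = models$offset, n_bins = 8))
  opt <- sm$phi_grid[which.max(sm$delta_p_sw)]
  ctl <- controller_config("switch", amplitude = 1e-9, pulse_target = "X",
                           target_state = target, optimal_onset = opt)
  log <- run_switch_control(xyz_config(), ctl, duration = 6, seed = 77,
                            models = models)
  list(time_in_target = log$time_in_target, baseline = baseline,
       target = target, log = log)
})

# adverse condition: strong depolarizing pulse into X at high noise while
# aiming at Tr^X — every onset phase lowers the switch probability there
adverse_switch_run <- function() fixture("adverse_switch_run", {
  net <- calibrated_network("xyz", noise_level = 0.15e-9, seed = 3)$config
  models <- ctcstim:::switch_models(net, seed = 5)
  pas <- simulate_network(net, 6, seed = 401)
  stt <- state_trace_offline(pas, offset = models$offset)
  baseline <- mean(stt$label == "TrX")
  ctl <- controller_config("switch", amplitude = 4e-9, pulse_target = "X",
                           target_state = "TrX", optimal_onset = 0)
  log <- run_switch_control(net, ctl, duration = 6, seed = 78,
                            models = models)
  list(time_in_target = log$time_in_target, baseline = baseline, log = log)
})
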