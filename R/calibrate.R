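# Drive-rate calibration: iteratively scale the afferent base rates (and,
# for the XYZ network, the feedforward connection probabilities onto Z)
# until pool firing rates match physiological targets at the given noise
# level. Noise inherently raises firing rates, so each noise level gets its
# own calibration.

#' Calibration targets
#'
#' @param rate_exc,rate_inh target mean rates (Hz; defaults 15 and 60).
#' @param tol_exc,tol_inh convergence tolerances (Hz).
#' @param max_iter iteration cap.
#' @param probe_duration duration of each probe simulation (s, >= 2).
#' @param learning_rate relative step per Hz of rate error (signed-error
#'   proportional update); each update is capped at \code{max_step}
#'   relative change per iteration.
#' @param max_step cap on the relative change per iteration.
#' @export
calibration_target <- function(rate_exc = 15, rate_inh = 60,
                               tol_exc = 1, tol_inh = 3, max_iter = 30,
                               probe_duration = 3, learning_rate = 0.02,
                               max_step = 0.2) {
  stopifnot(tol_exc > 0, tol_inh > 0, probe_duration >= 2)
  structure(list(rate_exc = rate_exc, rate_inh = rate_inh,
                 tol_exc = tol_exc, tol_inh = tol_inh, max_iter = max_iter,
                 probe_duration = probe_duration,
                 learning_rate = learning_rate, max_step = max_step),
            class = "ctc_cal_target")
}

# proportional multiplicative update, capped
cal_step <- function(value, err, target) {
  value * (1 + max(min(target$learning_rate * err, target$max_step),
                   -target$max_step))
}

pool_rate <- function(rates, pop, pool) rates$rate[rates$population == pop &
                                                     rates$pool == pool]

#' Calibrate afferent drive rates
#'
#' Iterates: simulate a probe, measure mean pool rates (first 0.5 s
#' discarded), scale each pool's base drive rate by an amount proportional
#' to the signed rate error (excitatory drive up when the excitatory rate
#' is low, inhibitory drive down when the inhibitory rate is high), stop
#' when both pools are within tolerance. For multi-column configs the
#' update uses the mean error over the driven columns (X/Y symmetry) and is
#' applied to all of them. Probe seeds follow a fixed per-iteration
#' sequence, so the loop is reproducible.
#'
#' @param config \code{ctc_config} (single column, column pair, or XYZ
#'   lower layer; populations with zero drive are ignored).
#' @param target \code{\link{calibration_target}}.
#' @param seed base seed of the probe sequence.
#' @param verbose print per-iteration diagnostics.
#' @return \code{ctc_calibration}: list(config [updated], rates
#'   c(rate_exc, rate_inh), achieved, iterations, converged).
#' @export
calibrate_drives <- function(config, target = calibration_target(),
                             seed = 1, verbose = FALSE) {
  driven <- names(config$drives)[vapply(config$drives, function(d)
    d$rate_exc > 0 || d$rate_inh > 0, logical(1))]
  if (!length(driven)) stop("no driven populations to calibrate")
  se <- config$drives[[driven[1]]]$rate_exc
  si <- config$drives[[driven[1]]]$rate_inh
  achieved <- c(NA_real_, NA_real_)
  converged <- FALSE
  for (k in seq_len(target$max_iter)) {
    for (id in driven) {
      config$drives[[id]]$rate_exc <- se
      config$drives[[id]]$rate_inh <- si
    }
    res <- simulate_network(config, target$probe_duration, seed = seed + k)
    rates <- mean_rates(res, skip = 0.5)
    re <- mean(vapply(driven, function(id) pool_rate(rates, id, "exc"),
                      numeric(1)))
    ri <- mean(vapply(driven, function(id) pool_rate(rates, id, "inh"),
                      numeric(1)))
    achieved <- c(rate_exc = re, rate_inh = ri)
    if (verbose)
      message(sprintf("iter %2d: S_e=%.0f S_i=%.0f -> exc %.2f Hz, inh %.2f Hz",
                      k, se, si, re, ri))
    if (abs(re - target$rate_exc) <= target$tol_exc &&
        abs(ri - target$rate_inh) <= target$tol_inh) {
      converged <- TRUE
      break
    }
    se <- cal_step(se, target$rate_exc - re, target)
    si <- cal_step(si, target$rate_inh - ri, target)
  }
  structure(list(config = config, rates = c(rate_exc = se, rate_inh = si),
                 achieved = achieved, iterations = k, converged = converged),
            class = "ctc_calibration")
}

#' @export
print.ctc_calibration <- function(x, ...) {
  cat("<ctc_calibration>", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations;",
      "achieved:", paste(signif(x$achieved, 4), collapse = " / "), "Hz\n")
  invisible(x)
}

#' Calibrate the feedforward connection probabilities onto Z
#'
#' With X and Y already calibrated, scales p_Ze along the Z excitatory-pool
#' rate error and p_Zi along the Z inhibitory-pool rate error (increasing a
#' probability increases the excitatory input to that pool), probabilities
#' clipped to [0, 1], until Z shows the same target rates.
#'
#' @param config XYZ \code{ctc_config}.
#' @param target \code{\link{calibration_target}}.
#' @param seed base probe seed.
#' @param verbose print per-iteration diagnostics.
#' @return \code{ctc_calibration} with element \code{probs}
#'   c(p_ze, p_zi); \code{converged = FALSE} with probabilities at a clip
#'   bound flags an unreachable target.
#' @export
calibrate_z_connectivity <- function(config, target = calibration_target(),
                                     seed = 1, verbose = FALSE) {
  idx_ze <- which(vapply(config$projections, function(p)
    p$target_pop == "Z" && p$target_pool == "exc" && p$source_pop != "Z",
    logical(1)))
  idx_zi <- which(vapply(config$projections, function(p)
    p$target_pop == "Z" && p$target_pool == "inh" && p$source_pop != "Z",
    logical(1)))
  if (!length(idx_ze) || !length(idx_zi))
    stop("config has no feedforward projections onto Z")
  p_ze <- config$projections[[idx_ze[1]]]$prob
  p_zi <- config$projections[[idx_zi[1]]]$prob
  achieved <- c(NA_real_, NA_real_)
  converged <- FALSE
  for (k in seq_len(target$max_iter)) {
    for (i in idx_ze) config$projections[[i]]$prob <- p_ze
    for (i in idx_zi) config$projections[[i]]$prob <- p_zi
    res <- simulate_network(config, target$probe_duration, seed = seed + 1000 + k)
    rates <- mean_rates(res, skip = 0.5)
    re <- pool_rate(rates, "Z", "exc")
    ri <- pool_rate(rates, "Z", "inh")
    achieved <- c(rate_exc = re, rate_inh = ri)
    if (verbose)
      message(sprintf("iter %2d: p_ze=%.3f p_zi=%.3f -> Z exc %.2f Hz, inh %.2f Hz",
                      k, p_ze, p_zi, re, ri))
    if (abs(re - target$rate_exc) <= target$tol_exc &&
        abs(ri - target$rate_inh) <= target$tol_inh) {
      converged <- TRUE
      break
    }
    at_bound <- (p_ze >= 1 && re < target$rate_exc) ||
      (p_ze <= 0 && re > target$rate_exc)
    p_ze <- min(max(cal_step(p_ze, target$rate_exc - re, target), 0), 1)
    p_zi <- min(max(cal_step(p_zi, target$rate_inh - ri, target), 0), 1)
    if (at_bound) break
  }
  structure(list(config = config, probs = c(p_ze = p_ze, p_zi = p_zi),
                 achieved = achieved, iterations = k, converged = converged),
            class = "ctc_calibration")
}

#' Fully calibrated configuration for a noise level
#'
#' Builds a single column / column pair / XYZ network and runs the drive
#' (and, for XYZ, Z-connectivity) calibration starting from the stored
#' defaults.
#'
#' @param kind "column", "pair" or "xyz".
#' @param noise_level sigma_n (A).
#' @param seed master seed.
#' @param target \code{\link{calibration_target}}.
#' @param verbose print diagnostics.
#' @return list(config, drives, probs, calibrations).
#' @export
calibrated_network <- function(kind = c("column", "pair", "xyz"),
                               noise_level = 0.075e-9, seed = 1,
                               target = calibration_target(),
                               verbose = FALSE) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    column = build_single_column(noise_level = noise_level, seed = seed),
    pair = build_column_pair(noise_level = noise_level, seed = seed),
    xyz = build_xyz_network(noise_level = noise_level, seed = seed))
  cal1 <- calibrate_drives(cfg, target, seed = seed, verbose = verbose)
  out <- list(config = cal1$config, drives = cal1$rates, probs = NULL,
              calibrations = list(drives = cal1))
  if (kind == "xyz") {
    cal2 <- calibrate_z_connectivity(cal1$config, target, seed = seed,
                                     verbose = verbose)
    out$config <- cal2$config
    out$probs <- cal2$probs
    out$calibrations$z <- cal2
  }
  out
}
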