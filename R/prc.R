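# Stochastic phase-response curves and state-switch probability maps,
# estimated from batches of short pulsed runs paired with unpulsed controls
# by onset phase (and, for the XYZ network, by network state).

#' Run a pulsed/control PRC experiment
#'
#' Simulates \code{n_runs} independent realizations per condition. Pulsed
#' runs receive one square pulse (1 ms) into \code{pulse_target} at
#' \code{pulse_time}; the control group (amplitude 0) shares the generator
#' settings but receives no pulse. For each run the offline phase of every
#' tracked population signal is computed (with the pulse window treated as
#' an artifact) and the onset phase is estimated from pre-pulse data only,
#' via the AR forecast method. Band and AR model are fitted once per
#' condition on a separate unperturbed training run.
#'
#' @param config \code{ctc_config} (calibrated).
#' @param amplitudes pulse amplitudes (A), e.g. \code{c(0, 1e-9)}; 0 is the
#'   control group and is added if missing.
#' @param n_runs runs per amplitude.
#' @param run_length run duration (s). @param pulse_time nominal pulse
#'   onset (s); must leave >= 0.4 s before it.
#' @param pulse_jitter per-run uniform jitter of the onset time (s). The
#'   network starts from identical initial conditions, so a deterministic
#'   onset would sample only a narrow range of oscillation phases; jitter
#'   over several gamma cycles makes the onset phase approximately uniform.
#' @param pulse_target population id to pulse; default the first.
#' @param track population/component pairs to compute phases for:
#'   named list id -> component ("exc_rate" or a current key); default the
#'   exc_rate of every population.
#' @param seed base seed; run r of amplitude j uses seed
#'   \code{seed + 1000*j + r}.
#' @param ar_train_duration training run length (s) for band/AR estimation.
#' @return \code{ctc_prc_batch}: list(trials, band, ar, config, ...).
#'   Each trial records onset_phase, state_at_onset (XYZ), amplitude and
#'   the offline \code{ctc_phase} per tracked signal.
#' @export
run_pulse_experiment <- function(config, amplitudes, n_runs = 300,
                                 run_length = 1, pulse_time = 0.5,
                                 pulse_jitter = 0.1,
                                 pulse_target = NULL, track = NULL,
                                 seed = 1, ar_train_duration = 10) {
  stopifnot(pulse_time >= 0.4,
            run_length - pulse_time - pulse_jitter >= 0.25)
  ids <- vapply(config$populations, `[[`, "", "id")
  pulse_target <- pulse_target %||% ids[1]
  track <- track %||% stats::setNames(as.list(rep("exc_rate", length(ids))), ids)
  if (!0 %in% amplitudes) amplitudes <- c(0, amplitudes)

  # condition-level band and AR model from an unperturbed training run
  train <- simulate_network(config, ar_train_duration, seed = seed * 7 + 3)
  tr_sig <- analysis_signal(train, pulse_target)
  band <- estimate_gamma_band(tr_sig)
  ar <- fit_ar(tr_sig, band = band)

  is_xyz <- all(c("X", "Y", "Z") %in% ids)
  state_ar <- NULL
  if (is_xyz) {
    state_ar <- lapply(c(xe = "X_exc", ye = "Y_exc", zi = "Z_inh"),
                       function(key) {
                         s <- analysis_signal(train, "Z",
                                              paste0("current_from:", key))
                         fit_ar(s, band = estimate_gamma_band(s))
                       })
  }

  trials <- list()
  discarded <- 0L
  for (j in seq_along(amplitudes)) {
    amp <- amplitudes[j]
    for (r in seq_len(n_runs)) {
      run_seed <- seed + 1000 * j + r
      onset_time <- pulse_time +
        round(with_local_seed(run_seed * 23 + 7,
                              stats::runif(1, 0, pulse_jitter)), 3)
      pulses <- if (amp != 0)
        list(stimulation_pulse(pulse_target, amp, onset_time)) else list()
      res <- simulate_network(config, run_length, pulses, seed = run_seed)
      # the zeroed window covers the pulse response transient; for PRC
      # reads the guard is the window itself (shifts at tau inside it are
      # unavailable, later ones usable)
      art <- if (amp != 0)
        list(c(onset_time, onset_time + res$pulses_applied[[1]]$duration + 0.01))
      else list()
      phases <- lapply(names(track), function(id) {
        offline_phase(analysis_signal(res, id, track[[id]]), band, art,
                      guard = 2e-3)
      })
      names(phases) <- names(track)
      if (is_xyz) {
        # offline phases of the Z-input currents and their differences:
        # the state phase-difference traces used for switch analysis
        keys <- c(xe = "X_exc", ye = "Y_exc", zi = "Z_inh")
        cph <- lapply(names(keys), function(nm)
          offline_phase(analysis_signal(res, "Z",
                                        paste0("current_from:", keys[[nm]])),
                        state_ar[[nm]]$band, art, guard = 2e-3))
        names(cph) <- names(keys)
        phases$state_zx <- structure(list(
          phase = wrap_angle(cph$xe$phase - cph$zi$phase), fs = 1000,
          valid = cph$xe$valid & cph$zi$valid, t0 = 0), class = "ctc_phase")
        phases$state_zy <- structure(list(
          phase = wrap_angle(cph$ye$phase - cph$zi$phase), fs = 1000,
          valid = cph$ye$valid & cph$zi$valid, t0 = 0), class = "ctc_phase")
      }
      # drop the last 2 ms of history: the centered 3 ms smoothing makes
      # them overlap the pulse response; the phase at onset is read 2
      # samples into the AR forecast instead
      pre <- round(onset_time * 1000) - 2L
      hist_sig <- analysis_signal(res, pulse_target)$samples[seq_len(pre)]
      onset <- tryCatch(realtime_phase(ar, analog_trace(hist_sig), band,
                                       read_offset = 2),
                        error = function(e) NA_real_)
      state <- NULL
      if (is_xyz) {
        oph <- vapply(c(xe = "X_exc", ye = "Y_exc", zi = "Z_inh"),
                      function(key) {
          s <- analysis_signal(res, "Z", paste0("current_from:", key))
          m <- state_ar[[match(key, c("X_exc", "Y_exc", "Z_inh"))]]
          tryCatch(realtime_phase(m, analog_trace(s$samples[seq_len(pre)]),
                                  m$band, read_offset = 2),
                   error = function(e) NA_real_)
        }, numeric(1))
        state <- c(phi_zx = wrap_angle(oph[["xe"]] - oph[["zi"]]),
                   phi_zy = wrap_angle(oph[["ye"]] - oph[["zi"]]))
      }
      if (is.na(onset)) {
        discarded <- discarded + 1L
        next
      }
      trials[[length(trials) + 1L]] <- list(
        amplitude = amp, onset_time = onset_time, onset_phase = onset,
        state_at_onset = state, phases = phases, seed = run_seed)
    }
  }
  if (discarded > 0)
    message(discarded, " trial(s) discarded (invalid onset phase)")
  structure(list(trials = trials, band = band, ar = ar, config = config,
                 pulse_time = pulse_time, pulse_target = pulse_target,
                 amplitudes = amplitudes, discarded = discarded),
            class = "ctc_prc_batch")
}

#' @export
print.ctc_prc_batch <- function(x, ...) {
  cat("<ctc_prc_batch>", length(x$trials), "trials; amplitudes (nA):",
      paste(signif(x$amplitudes * 1e9, 3), collapse = ", "), "\n")
  invisible(x)
}

batch_subset <- function(batch, amplitude) {
  Filter(function(t) t$amplitude == amplitude, batch$trials)
}

#' Pair pulsed trials with controls and compute phase shifts
#'
#' Greedy one-to-one matching (pulsed trials in order, ties by index)
#' minimizing the circular onset-phase distance; XYZ trials additionally
#' require both state phase differences at onset to match within
#' \code{state_tol}. The phase shift at delay tau is the circular
#' difference between the pulsed and matched control phase at
#' \code{pulse_time + tau}.
#'
#' @param pulsed_trials,control_trials trial lists (see
#'   \code{\link{run_pulse_experiment}}).
#' @param tau_grid delays after pulse onset (s).
#' @param signal which tracked phase signal to difference (population id).
#' @param state_tol matching tolerance (rad) for each state phase
#'   difference.
#' @return data.frame: phi (onset phase of the pulsed trial), tau, dphi
#'   (circular shift), plus the matched control onset phase. A warning is
#'   issued if more than 20 percent of pulsed trials remain unmatched.
#' @export
pair_and_shift <- function(pulsed_trials, control_trials,
                           tau_grid = seq(0, 0.15, by = 5e-3),
                           signal = NULL, state_tol = 0.2) {
  if (!length(pulsed_trials) || !length(control_trials))
    stop("both trial groups must be nonempty")
  signal <- signal %||% names(pulsed_trials[[1]]$phases)[1]
  ctrl_phi <- vapply(control_trials, `[[`, numeric(1), "onset_phase")
  used <- rep(FALSE, length(control_trials))
  has_state <- !is.null(pulsed_trials[[1]]$state_at_onset)
  rows <- vector("list", length(pulsed_trials))
  unmatched <- 0L
  for (i in seq_along(pulsed_trials)) {
    tr <- pulsed_trials[[i]]
    d <- circ_dist(ctrl_phi, tr$onset_phase)
    d[used] <- Inf
    if (has_state) {
      ok <- vapply(control_trials, function(ct) {
        s1 <- tr$state_at_onset; s2 <- ct$state_at_onset
        !any(is.na(c(s1, s2))) &&
          circ_dist(s1[["phi_zx"]], s2[["phi_zx"]]) <= state_tol &&
          circ_dist(s1[["phi_zy"]], s2[["phi_zy"]]) <= state_tol
      }, logical(1))
      d[!ok] <- Inf
    }
    j <- which.min(d)
    if (!is.finite(d[j])) {
      unmatched <- unmatched + 1L
      next
    }
    used[j] <- TRUE
    ct <- control_trials[[j]]
    dphi <- vapply(tau_grid, function(tau) {
      p1 <- phase_at(tr$phases[[signal]], tr$onset_time + tau)
      p0 <- phase_at(ct$phases[[signal]], ct$onset_time + tau)
      if (is.na(p1) || is.na(p0)) NA_real_ else wrap_angle(p1 - p0)
    }, numeric(1))
    rows[[i]] <- data.frame(phi = tr$onset_phase, tau = tau_grid,
                            dphi = dphi, control_phi = ct$onset_phase)
  }
  if (unmatched > 0.2 * length(pulsed_trials))
    warning(sprintf("%d of %d pulsed trials unmatched", unmatched,
                    length(pulsed_trials)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[!is.na(out$dphi), ]
}

#' Estimate the PRC density and mean PRC at one delay
#'
#' Histograms the shifts into an onset-phase x shift grid (36 x 36 bins,
#' no smoothing) and condenses each occupied onset-phase bin into circular
#' mean, resultant length and circular 25th/75th percentiles. Bins with
#' fewer than \code{min_n} samples, or resultant below 0.1, are flagged
#' undefined rather than interpolated.
#'
#' @param shifts data.frame from \code{\link{pair_and_shift}}.
#' @param tau delay to select (s); NA selects all rows.
#' @param n_bins grid size. @param min_n minimum samples per reported bin.
#' @return list of class \code{ctc_prc}: phi_grid (bin centers), density
#'   (n_bins x n_bins, columns normalized per phi bin), mean_shift, q25,
#'   q75, resultant, n, defined, tau.
#' @export
estimate_prc_density <- function(shifts, tau = NA, n_bins = 36, min_n = 10) {
  if (!is.na(tau)) shifts <- shifts[abs(shifts$tau - tau) < 1e-9, ]
  brk <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  bin <- function(x) pmin(pmax(findInterval(wrap_angle(x), brk,
                                            rightmost.closed = TRUE), 1), n_bins)
  bphi <- bin(shifts$phi)
  bshift <- bin(shifts$dphi)
  dens <- matrix(0, n_bins, n_bins,
                 dimnames = list(shift = NULL, phi = NULL))
  for (i in seq_along(bphi)) dens[bshift[i], bphi[i]] <-
      dens[bshift[i], bphi[i]] + 1
  n_per <- colSums(dens)
  dens <- sweep(dens, 2, pmax(n_per, 1), "/")
  ms <- q25 <- q75 <- rs <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    v <- shifts$dphi[bphi == b]
    if (length(v)) {
      cs <- circular_stats(v)
      ms[b] <- cs$mean; q25[b] <- cs$q25; q75[b] <- cs$q75
      rs[b] <- cs$resultant
    }
  }
  defined <- n_per >= min_n & !is.na(rs) & rs > 0.1
  structure(list(phi_grid = centers, density = dens, mean_shift = ms,
                 q25 = q25, q75 = q75, resultant = rs, n = n_per,
                 defined = defined, tau = tau), class = "ctc_prc")
}

#' @export
print.ctc_prc <- function(x, ...) {
  cat("<ctc_prc> tau =", x$tau, "s;", sum(x$defined), "of",
      length(x$phi_grid), "phase bins defined\n")
  invisible(x)
}

#' Switch probability from a state-shift distribution
#'
#' The probability that a shift of the network phase difference leaves the
#' basin of the current state:
#' \eqn{p_{sw} = 1 - \int_{-\pi/2}^{\pi/2} \rho(\Delta\Phi) d\Delta\Phi},
#' estimated as the fraction of samples with \eqn{|\Delta\Phi| > \pi/2}.
#'
#' @param dphi state-difference shifts (radians).
#' @return probability in [0, 1].
#' @export
switch_probability <- function(dphi) {
  dphi <- dphi[!is.na(dphi)]
  if (!length(dphi)) stop("empty shift sample")
  mean(abs(wrap_angle(dphi)) > pi / 2)
}

#' Switch-probability map over onset phase
#'
#' Bins pulsed state shifts by onset phase and reports, per bin, the switch
#' probability and its change over the passive (control-vs-control)
#' baseline at the same delay.
#'
#' @param shifts pulsed shift samples (data.frame phi/tau/dphi) of the
#'   state phase difference.
#' @param passive_shifts control-vs-control shift samples at matching
#'   delays.
#' @param tau delay to select (s).
#' @param n_bins onset-phase bins.
#' @return list of class \code{ctc_switchmap}: phi_grid, p_sw, delta_p_sw,
#'   p_passive, n, tau.
#' @export
switch_map <- function(shifts, passive_shifts, tau, n_bins = 36) {
  sel <- abs(shifts$tau - tau) < 1e-9
  psel <- abs(passive_shifts$tau - tau) < 1e-9
  if (!any(sel) || !any(psel)) stop("no samples at the requested delay")
  p_passive <- switch_probability(passive_shifts$dphi[psel])
  brk <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  b <- pmin(pmax(findInterval(wrap_angle(shifts$phi[sel]), brk,
                              rightmost.closed = TRUE), 1), n_bins)
  dp <- shifts$dphi[sel]
  p_sw <- n <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    v <- dp[b == k]
    n[k] <- length(v)
    if (length(v)) p_sw[k] <- switch_probability(v)
  }
  structure(list(phi_grid = centers, p_sw = p_sw,
                 delta_p_sw = p_sw - p_passive, p_passive = p_passive,
                 n = n, tau = tau), class = "ctc_switchmap")
}

#' Settling delay of the mean PRC
#'
#' The smallest delay tau after which consecutive mean-PRC curves stop
#' changing: circular distance between successive curves, averaged over
#' onset-phase bins defined in both, stays below \code{tolerance} for all
#' later delays.
#'
#' @param prcs list of \code{ctc_prc} at increasing tau (grid spacing
#'   <= 5 ms recommended).
#' @param tolerance mean circular distance threshold (rad).
#' @return list(settled, tau); \code{tau} is NA when the curves never
#'   stabilize within the grid.
#' @export
settle_time <- function(prcs, tolerance = 0.15) {
  taus <- vapply(prcs, `[[`, numeric(1), "tau")
  stopifnot(!is.unsorted(taus))
  nd <- length(prcs) - 1
  dists <- vapply(seq_len(nd), function(i) {
    a <- prcs[[i]]; b <- prcs[[i + 1]]
    ok <- a$defined & b$defined
    if (!any(ok)) return(NA_real_)
    mean(circ_dist(a$mean_shift[ok], b$mean_shift[ok]))
  }, numeric(1))
  below <- !is.na(dists) & dists < tolerance
  stable_from <- NA_integer_
  for (i in seq_len(nd)) {
    if (all(below[i:nd])) { stable_from <- i; break }
  }
  if (is.na(stable_from)) return(list(settled = FALSE, tau = NA_real_,
                                      dists = dists))
  list(settled = TRUE, tau = taus[stable_from], dists = dists)
}

#' Mean PRCs on a delay grid from a PRC batch
#'
#' @param batch \code{ctc_prc_batch}. @param amplitude amplitude (A) of
#'   the pulsed group. @param tau_grid delays (s). @param signal tracked
#'   signal id. @param ... forwarded to \code{\link{estimate_prc_density}}.
#' @return list(prcs [one ctc_prc per tau], shifts).
#' @export
prc_by_tau <- function(batch, amplitude, tau_grid = seq(0, 0.1, by = 5e-3),
                       signal = NULL, ...) {
  shifts <- pair_and_shift(batch_subset(batch, amplitude),
                           batch_subset(batch, 0), tau_grid,
                           signal = signal)
  prcs <- lapply(tau_grid, function(tau)
    estimate_prc_density(shifts, tau, ...))
  list(prcs = prcs, shifts = shifts)
}
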