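# PRC estimation tested on constructed phase traces with known answers;
# simulation-backed PRC behavior is covered by the acceptance suite.

tau_grid <- seq(0, 0.15, by = 5e-3)

test_that("self-pairing of the control group yields zero shifts", {
  trials <- lapply(seq(-3, 3, length.out = 20), function(p)
    synth_trial(p, amplitude = 0))
  sh <- pair_and_shift(trials, trials, tau_grid)
  expect_true(all(abs(sh$dphi) < 1e-9))
})

test_that("a constant post-pulse offset is recovered at every delay", {
  grid <- seq(-3, 3, length.out = 30)
  ctrl <- lapply(grid, function(p) synth_trial(p))
  # pulsed trace = control trace + pi/4 from the onset onward, with the
  # same onset phase (0.5 s spans an integer number of 60 Hz cycles)
  puls <- lapply(grid, function(p)
    synth_trial(p, amplitude = 1e-9, t_reset = 0.5,
                reset_to = wrap_angle(p + pi / 4)))
  sh <- pair_and_shift(puls, ctrl, tau_grid)
  expect_true(all(abs(wrap_angle(sh$dphi - pi / 4)) < 1e-6))
})

test_that("shifts wrap correctly across the pi boundary", {
  ctrl <- list(synth_trial(pi - 0.1 - 2 * pi * 60 * 0.5))
  puls <- list(synth_trial(-pi + 0.1 - 2 * pi * 60 * 0.5, amplitude = 1e-9))
  # both trials share frequency, so at every delay the difference is the
  # initial separation: +0.2 through the boundary, not -2*pi + 0.2
  sh <- pair_and_shift(puls, ctrl, tau_grid)
  expect_true(all(abs(sh$dphi - 0.2) < 1e-6))
})

test_that("a full phase reset produces a slope -1 mean PRC", {
  set.seed(31)
  phis <- runif(400, -pi, pi)
  c_reset <- 1.1
  ctrl <- lapply(runif(400, -pi, pi), synth_trial)
  puls <- lapply(phis, function(p)
    synth_trial(p, amplitude = 4e-9, t_reset = 0.5, reset_to = c_reset))
  sh <- pair_and_shift(puls, ctrl, 0.1)
  prc <- estimate_prc_density(sh, 0.1, min_n = 3)
  ok <- prc$defined
  expect_gt(sum(ok), 20)
  # closed-form reset map: mean shift = wrap(c - phi) up to matching noise
  pred <- wrap_angle(c_reset + 2 * pi * 60 * 0.1 - prc$phi_grid[ok])
  expect_lt(mean(circ_dist(prc$mean_shift[ok], pred)), 0.2)
  # circular regression against slope -1: rotate out the line and the
  # residual concentration should be near 1
  resid <- wrap_angle(prc$mean_shift[ok] + prc$phi_grid[ok])
  expect_gt(circular_stats(resid)$resultant, 0.95)
})

test_that("conditional densities normalize per onset-phase column", {
  set.seed(32)
  sh <- data.frame(phi = runif(500, -pi, pi), tau = 0.1,
                   dphi = runif(500, -pi, pi))
  prc <- estimate_prc_density(sh, 0.1)
  cs <- colSums(prc$density)
  expect_true(all(abs(cs[prc$n > 0] - 1) < 1e-12))
  expect_true(all(prc$n[colSums(prc$density) == 0] == 0))
})

test_that("switch probability matches analytic cases", {
  expect_equal(switch_probability(rep(0, 100)), 0)
  expect_equal(switch_probability(rep(pi, 100)), 1)
  # uniform density: the in-basin integral over (-pi/2, pi/2) is 1/2
  u <- seq(-pi + 1e-6, pi, length.out = 10000)
  expect_equal(switch_probability(u), 0.5, tolerance = 1e-3)
  expect_error(switch_probability(numeric(0)), "empty")
})

test_that("switch maps report the change over the passive baseline", {
  set.seed(33)
  n <- 400
  sh <- data.frame(phi = runif(n, -pi, pi), tau = 0.1,
                   dphi = rep(pi, n))                  # always switches
  passive <- data.frame(phi = runif(n, -pi, pi), tau = 0.1,
                        dphi = rep(0, n))              # never switches
  sm <- switch_map(sh, passive, 0.1, n_bins = 6)
  expect_equal(sm$p_passive, 0)
  expect_true(all(sm$p_sw[sm$n > 0] == 1))
  expect_true(all(sm$delta_p_sw[sm$n > 0] == 1))
})

test_that("settle time is the first delay after which the PRC stops moving", {
  mk <- function(tau, rot) {
    g <- seq(-pi, pi, length.out = 37)[-37] + pi / 36
    structure(list(phi_grid = g, mean_shift = wrap_angle(g + rot),
                   q25 = g, q75 = g, resultant = rep(1, 36),
                   n = rep(20, 36), defined = rep(TRUE, 36), tau = tau),
              class = "ctc_prc")
  }
  taus <- seq(0, 0.1, 5e-3)
  # constant family: settled at the first grid point
  st <- settle_time(lapply(taus, mk, rot = 0.3))
  expect_true(st$settled)
  expect_equal(st$tau, 0)
  # converging family: rotation decays to a fixed point by 30 ms
  rots <- ifelse(taus < 0.03, 1 - taus / 0.03, 0)
  st2 <- settle_time(Map(mk, taus, rots))
  expect_true(st2$settled)
  expect_equal(st2$tau, 0.03, tolerance = 0.011)
  # drifting family: never converges
  st3 <- settle_time(Map(mk, taus, 40 * taus))
  expect_false(st3$settled)
  expect_true(is.na(st3$tau))
})
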