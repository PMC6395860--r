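test_that("routing-state classification follows the interval rule", {
  expect_equal(classify_state(0.25 * pi, 0.25 * pi - pi)$label, "TrX")
  expect_equal(classify_state(pi, 0.25 * pi)$label, "TrY")
  expect_equal(classify_state(0.75 * pi, -0.25 * pi)$label, "transition")
  expect_equal(classify_state(NA, 0.2)$label, "unknown")
  # the reference offset rotates the favorable window
  expect_equal(classify_state(-0.65, 0.25 * pi - pi,
                              offset = 0.25 * pi + 0.65)$label, "TrX")
})

test_that("phase crossings are edge-triggered without wrap artifacts", {
  expect_true(ctcstim:::phase_crossed(-0.1, 0.05, 0))
  expect_false(ctcstim:::phase_crossed(0.05, 0.1, 0))     # already past
  expect_false(ctcstim:::phase_crossed(pi - 0.05, -pi + 0.05, 0))  # wrap jump
  expect_false(ctcstim:::phase_crossed(NA, 0.05, 0))
})

make_prc <- function(shifts) {
  g <- seq(-pi, pi, length.out = length(shifts) + 1)
  g <- g[-length(g)] + diff(g[1:2]) / 2
  structure(list(phi_grid = g, mean_shift = shifts,
                 q25 = shifts, q75 = shifts,
                 resultant = rep(1, length(shifts)),
                 n = rep(50, length(shifts)),
                 defined = rep(TRUE, length(shifts)), tau = 0.1),
            class = "ctc_prc")
}

test_that("sync controller inverts the PRC to choose the onset phase", {
  shifts <- c(0.6, 0.3, 0, -0.3, -0.6, -1.2, -1.57, -0.9)
  cfg <- controller_config("sync", prc = make_prc(shifts), amplitude = 1e-9)
  # in-window: no action
  dec <- sync_controller(0.1, 0, cfg, t = 1)
  expect_false(dec$fire)
  # phi_xy = pi/2 requires a -pi/2 shift; the tabulated -1.57 bin is exact
  dec <- sync_controller(pi / 2, 0, cfg, t = 1, phi_x_prev = NA)
  expect_equal(dec$required_shift, -pi / 2, tolerance = 1e-9)
  expect_equal(dec$onset_phase, make_prc(shifts)$phi_grid[7])
  # fires only when the live phase crosses that onset
  dec2 <- sync_controller(dec$onset_phase + 0.01, 0, cfg, t = 1,
                          phi_x_prev = dec$onset_phase - 0.05)
  expect_true(dec2$fire)
  # refractory blocks everything
  dec3 <- sync_controller(dec$onset_phase + 0.01, 0, cfg, t = 1,
                          last_pulse = 0.95,
                          phi_x_prev = dec$onset_phase - 0.05)
  expect_false(dec3$fire)
})

test_that("sync controller degrades to threshold-only pulsing when the PRC is undefined", {
  prc <- make_prc(rep(0.5, 8))
  prc$defined[] <- FALSE
  cfg <- controller_config("sync", prc = prc)
  dec <- sync_controller(pi / 2, 0, cfg, t = 1)
  expect_true(dec$fire)
  expect_true(dec$fallback)
})

test_that("switch controller fires only out of state, after refractory, at the onset", {
  cfg <- controller_config("switch", target_state = "TrX",
                           optimal_onset = 0.3)
  in_state <- classify_state(0.25 * pi, 0.25 * pi - pi)
  out_state <- classify_state(pi, 0.25 * pi)
  expect_false(switch_controller(in_state, 0.31, cfg, t = 1,
                                 phi_prev = 0.25))
  expect_false(switch_controller(out_state, 0.31, cfg, t = 1,
                                 last_pulse = 0.95, phi_prev = 0.25))
  expect_true(switch_controller(out_state, 0.31, cfg, t = 1,
                                phi_prev = 0.25))
  # a phase sweep through the onset fires exactly once
  sweep <- seq(-pi + 0.01, pi, length.out = 60)
  fired <- sum(vapply(2:60, function(i)
    switch_controller(out_state, sweep[i], cfg, t = 1,
                      phi_prev = sweep[i - 1]), logical(1)))
  expect_equal(fired, 1)
  expect_false(switch_controller(classify_state(NA, NA), 0.31, cfg, t = 1,
                                 phi_prev = 0.25))
})

test_that("controller configuration validates its bounds", {
  expect_error(controller_config("sync", threshold = 0), "threshold")
  expect_error(controller_config("sync", tau_ref = 0))
  expect_error(controller_config("nonsense"))
})

test_that("performance evaluation refuses unequal run durations", {
  lg <- structure(list(result = list(duration = 10)), class = "ctc_control_log")
  pr <- structure(list(duration = 8), class = "ctc_result")
  expect_error(evaluate_performance(list(lg), list(pr)), "equal durations")
})
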