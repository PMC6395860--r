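test_that("single-column builder wires the ING motif", {
  cfg <- build_single_column(noise_level = 0.075e-9, seed = 1)
  expect_length(cfg$projections, 2)
  for (pr in cfg$projections) {
    expect_equal(pr$kind, "inhibitory")
    expect_equal(pr$prob, 0.5)
    expect_equal(pr$delay, 5e-3)
    expect_equal(pr$source_pool, "inh")
  }
  expect_equal(cfg$populations[[1]]$n_exc, 800L)
  expect_equal(cfg$populations[[1]]$n_inh, 200L)
  expect_error(population_params("a", V_thresh = -0.07, V_reset = -0.06),
               "V_reset")
  expect_error(synapse_params(tau_e = -1), "taus")
  expect_error(projection("a", "inh", "b", "exc", 0.5, 5e-3, "excitatory"),
               "match the source pool")
})

test_that("XYZ builder has feedforward-only output column and correct cross wiring", {
  cfg <- build_xyz_network(p_ze = 0.1, p_zi = 0.1, seed = 1)
  from_z <- Filter(function(p) p$source_pop == "Z" &&
                     p$target_pop != "Z", cfg$projections)
  expect_length(from_z, 0)
  cross <- Filter(function(p) p$source_pop != p$target_pop, cfg$projections)
  expect_length(cross, 6)  # X<->Y lateral plus 4 feedforward onto Z
  lat <- Filter(function(p) p$target_pop %in% c("X", "Y"), cross)
  for (pr in lat) {
    expect_equal(pr$prob, 0.02)
    expect_equal(pr$target_pool, "inh")
  }
})

test_that("realized synapse counts match the binomial expectation", {
  cfg <- build_xyz_network(p_ze = 0.1, p_zi = 0.1, seed = 5)
  sess <- sim_session(cfg, 0.01, seed = 5)
  adj <- ctcstim:::.sim_adjacency(sess$ptr)
  found <- FALSE
  for (a in adj) {
    if (a$source == "X_exc" && a$target == "Y_inh") {
      found <- TRUE
      n <- 800 * 200
      expect_lt(abs(a$n_synapses - n * 0.02),
                qnorm(0.995) * sqrt(n * 0.02 * 0.98))
    }
  }
  expect_true(found)
})

test_that("adjacency is reproducible under a fixed structural seed", {
  cfg <- build_single_column(noise_level = 0, seed = 9)
  a1 <- ctcstim:::.sim_adjacency(sim_session(cfg, 0.01, seed = 1)$ptr)
  a2 <- ctcstim:::.sim_adjacency(sim_session(cfg, 0.01, seed = 2)$ptr)
  expect_identical(a1, a2)
})

test_that("quiescent membrane settles at the stable root of the quadratic", {
  # independent oracle: root of p2 V^2 + p1 V + p0 nearest V_reset
  rts <- Re(polyroot(c(3.89e-9, 1.30e-7, 1.08e-6)))
  v_star <- rts[which.min(abs(rts - (-67e-3)))]
  expect_equal(v_star, -64.7e-3, tolerance = 1e-3)
  cfg <- build_single_column(noise_level = 0, seed = 1,
                             drive_rates = c(rate_exc = 0, rate_inh = 0))
  sess <- sim_session(cfg, 1, seed = 1)
  session_step(sess, 1000)
  res <- collect_result(sess)
  expect_equal(nrow(res$spikes), 0)
  v <- ctcstim:::.sim_membrane(sess$ptr)
  expect_lt(max(abs(v - v_star)), 1e-4)
})

test_that("without synapses the trajectory matches a scalar Euler oracle", {
  cfg <- build_single_column(noise_level = 0, seed = 1,
                             drive_rates = c(rate_exc = 0, rate_inh = 0))
  sess <- sim_session(cfg, 0.05, seed = 1)
  session_step(sess, 50)
  v_sim <- ctcstim:::.sim_membrane(sess$ptr)[1]
  # standalone 1-D forward Euler of C dV/dt = p2 V^2 + p1 V + p0
  v <- -67e-3
  C <- 1e-6 * 2.88e-4
  for (k in 1:500)
    v <- v + 1e-4 * (1.08e-6 * v^2 + 1.30e-7 * v + 3.89e-9) / C
  expect_equal(v_sim, v, tolerance = 1e-12)
})

test_that("spikes are delivered to targets exactly one projection delay later", {
  # drive only the inhibitory pool; the first I->E current must appear
  # 5 ms after the first inhibitory spike, not before
  cfg <- build_single_column(noise_level = 0, seed = 1, sigma_f = 0,
                             drive_rates = c(rate_exc = 0, rate_inh = 8000))
  res <- simulate_network(cfg, 0.2, seed = 3)
  isp <- res$spikes[res$spikes$pool == "inh", ]
  expect_gt(nrow(isp), 0)
  t_first <- min(isp$time)
  cur <- res$signals_1khz$col$currents$col_inh
  first_ms <- which(abs(cur) > 0)[1]        # 1-based ms bins
  expect_gte((first_ms - 1) / 1000, t_first + 5e-3 - 1.5e-3)
  expect_lte((first_ms - 1) / 1000, t_first + 5e-3 + 1.5e-3)
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  cfg <- build_single_column(noise_level = 0.075e-9, seed = 4)
  p <- list(stimulation_pulse("col", 1e-9, 0.3))
  r1 <- simulate_network(cfg, 0.6, p, seed = 21)
  r2 <- simulate_network(cfg, 0.6, p, seed = 21)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$signals_1khz, r2$signals_1khz)
  r3 <- simulate_network(cfg, 0.6, p, seed = 22)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a strong depolarizing pulse discharges the whole quiescent column", {
  cfg <- build_single_column(noise_level = 0, seed = 1,
                             drive_rates = c(rate_exc = 0, rate_inh = 0))
  res <- simulate_network(cfg, 0.2,
                          list(stimulation_pulse("col", 4e-9, 0.1)), seed = 1)
  sp <- res$spikes
  expect_gte(nrow(sp), 1000)               # every neuron fires at least once
  expect_true(all(sp$time >= 0.1 & sp$time < 0.115))
})

test_that("numeric divergence raises an informative integration error", {
  cfg <- build_single_column(noise_level = 0, seed = 1,
                             drive_rates = c(rate_exc = 0, rate_inh = 0))
  expect_error(simulate_network(cfg, 0.05,
                                list(stimulation_pulse("col", -1e-5, 0.01,
                                                       duration = 0.02))),
               "diverged")
})

test_that("rate signals follow their definition", {
  cfg <- build_single_column(noise_level = 0, seed = 1,
                             drive_rates = c(rate_exc = 0, rate_inh = 0))
  res <- simulate_network(cfg, 0.2,
                          list(stimulation_pulse("col", 4e-9, 0.05)), seed = 1)
  tr <- extract_population_signal(res, "col", "exc_rate")
  # all 800 exc neurons spike once within the pulse millisecond
  expect_equal(max(tr$samples), 1000)
  # empty raster before the pulse
  expect_true(all(tr$samples[1:45] == 0))
  expect_error(extract_population_signal(res, "col", "nonsense"), "component")
  expect_error(extract_population_signal(res, "nope", "exc_rate"), "population")
})
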