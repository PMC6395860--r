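test_that("experiment bundles are written with tables and a manifest", {
  b <- structure(list(name = "phase_error", scale = "desk", seed = 1,
                      tables = list(tab = data.frame(x = 1:3, y = c(2, 4, 6))),
                      meta = list(tables = "tab")), class = "ctc_bundle")
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "tab.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$name, "phase_error")
  expect_equal(man$seed, 1L)
  s <- summarize_bundle(b)
  expect_equal(s$mean[s$measure == "y"], 4)
  unlink(dir, recursive = TRUE)
})

test_that("unknown experiment names are rejected", {
  expect_error(run_experiment("nonsense"), "arg")
})

test_that("the real-time phase error experiment runs at reduced scale", {
  b <- run_experiment("phase_error", "desk", seed = 2,
                      overrides = list(noise_grid = 0.075e-9, duration = 4,
                                       n_probe = 10))
  tb <- b$tables$phase_error
  expect_equal(nrow(tb), 1)
  expect_gt(tb$n, 5)
  # the real-time estimate agrees with the offline one on average
  expect_lt(abs(tb$mean_diff), 0.4)
  expect_gt(tb$resultant, 0.7)
})

test_that("routing scores are state-conditioned and NA below the sample floor", {
  run <- xyz_passive()[[1]]
  rs <- run$scores
  expect_equal(rs$state, c("all", "TrX", "TrY"))
  expect_true(all(rs$sc_x[!is.na(rs$sc_x)] >= 0 &
                    rs$sc_x[!is.na(rs$sc_x)] <= 1))
  rs2 <- routing_scores(run$result, run$stt, min_ms = Inf)
  expect_true(all(is.na(rs2$sc_x[rs2$state != "all"])))
})
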