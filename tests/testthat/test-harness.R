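test_that("the full design produces 64 runs and restricted designs scale down", {
  design <- experiment_design(harness_config(), seed = 1)
  expect_equal(nrow(design$runs), 64L)
  small <- experiment_design(harness_config(), conditions = 1, sessions = "A",
                             seed = 1)
  expect_equal(nrow(small$runs), 8L)
})

test_that("the harness is deterministic under the design seed", {
  design <- experiment_design(harness_config(), conditions = 1:2,
                              sessions = c("A", "B"), seed = 11)
  run_a <- run_harness(design)
  run_b <- run_harness(design)
  expect_identical(run_a, run_b)
  expect_equal(nrow(run_a), 32L)
  expect_true(all(is.na(run_a$peak_to_peak_drop[run_a$mode == "constant"])))
  expect_true(all(is.finite(run_a$peak_to_peak_drop[run_a$mode == "pulsatile"])))
})

test_that("identical sessions give perfect between-session agreement", {
  design <- experiment_design(harness_config(), conditions = 1:2,
                              sessions = "A", seed = 3)
  tbl <- run_harness(design)
  mirrored <- tbl
  mirrored$session <- "B"
  both <- rbind(tbl, mirrored)
  for (met in c("peak_drop", "net_drop", "peak_to_peak_drop")) {
    sc <- session_comparison(both, met, "pulsatile")
    expect_equal(sc$r_squared, 1, tolerance = 1e-12)
    expect_equal(sc$bias, 0, tolerance = 1e-12)
  }
})

test_that("the day-2 obstruction bias is positive for the instantaneous metrics", {
  design <- experiment_design(harness_config(), seed = 5)
  tbl <- run_harness(design)
  for (mode in c("pulsatile", "constant")) {
    expect_gt(session_comparison(tbl, "peak_drop", mode)$bias, 0)
    expect_gt(session_comparison(tbl, "net_drop", mode)$bias, 0)
  }
})

test_that("unmatched session pairs are reported", {
  design <- experiment_design(harness_config(), conditions = 1,
                              sessions = c("A", "B"), seed = 2)
  tbl <- run_harness(design)
  broken <- tbl[-which(tbl$session == "B" & tbl$peak_flow == 150 &
                         tbl$mode == "pulsatile"), ]
  expect_error(session_comparison(broken, "peak_drop", "pulsatile"), "unmatched")
  expect_error(session_comparison(tbl, "peak_to_peak_drop", "constant"),
               "not defined")
})

test_that("a metric regressed on itself gives slope 1 and net-vs-peak follows the recovery law", {
  cfg <- harness_config(inertial_coefficient = 0, reflection_coefficient = 0,
                        noise_broadband_sd = 0.1, turbulence_noise_amplitude = 0,
                        pump_artifact_amplitude = 0, recovery_noise_rel = 0)
  cfg <- set_orifice_ratio(cfg, 0.245)
  design <- experiment_design(cfg, conditions = 1, sessions = "A", seed = 9)
  tbl <- run_harness(design)
  self <- metric_relation(tbl, "peak_drop", "peak_drop", "pulsatile")
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_equal(self$r_squared, 1, tolerance = 1e-12)
  rel <- metric_relation(tbl, "peak_drop", "net_drop", "pulsatile")
  expect_equal(rel$slope, 0.63, tolerance = 0.02 / 0.63)
  expect_gt(rel$r_squared, 0.99)
})

test_that("peak-to-peak relates worse to the other metrics than they do to each other", {
  design <- experiment_design(harness_config(), seed = 13)
  tbl <- run_harness(design)
  r2_net_peak <- metric_relation(tbl, "peak_drop", "net_drop", "pulsatile")$r_squared
  r2_p2p_net <- metric_relation(tbl, "net_drop", "peak_to_peak_drop",
                                "pulsatile")$r_squared
  expect_gt(r2_net_peak, r2_p2p_net)
})
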