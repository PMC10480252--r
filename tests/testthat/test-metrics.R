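make_avg <- function(p_ref, p_dist, fs = 1000) {
  n <- length(p_ref)
  pressures <- matrix(rep(p_ref, 7), ncol = 7)
  pressures <- cbind(pressures[, 1:6], p_dist)
  list(pressures = pressures, phase_time = (seq_len(n) - 1) / fs)
}

test_that("the peak-drop instant is the maximum of the reference-distal difference", {
  n <- 1000
  t <- (seq_len(n) - 1) / 1000
  bump <- 5 * exp(-(t - 0.37)^2 / (2 * 0.02^2))
  avg <- make_avg(p_ref = rep(100, n), p_dist = 100 - bump)
  t_star <- find_peak_drop_instant(avg, 1, 7)
  expect_equal(as.numeric(t_star), 0.37, tolerance = 1e-3)
})

test_that("ties break to the earliest instant and identical channels give zero drop", {
  n <- 500
  avg <- make_avg(rep(80, n), rep(80, n))
  t_star <- find_peak_drop_instant(avg, 1, 7)
  expect_equal(as.numeric(t_star), 0)
  expect_equal(attr(t_star, "index"), 1L)
})

test_that("identical constant pressures yield all-zero metrics", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  avg <- ensemble_average(rec, segment_cycles(rec))
  avg$pressures[] <- 90
  m <- extract_metrics(avg)
  expect_equal(m$peak_drop, 0, tolerance = 1e-9)
  expect_equal(m$net_drop, 0, tolerance = 1e-9)
  expect_equal(m$peak_to_peak_drop, 0, tolerance = 1e-9)
})

test_that("the quasi-steady phantom at r = 0.245 reproduces the 0.63 net-to-peak ratio", {
  cfg <- quiet_config(inertial_coefficient = 0)
  cfg <- set_orifice_ratio(cfg, 0.245)
  m <- analyze_recording(simulate_recording(cfg, flow_condition("pulsatile", 250)))
  expect_equal(m$net_drop / m$peak_drop, 0.63, tolerance = 0.02 / 0.63)
  expect_lt(abs(m$peak_location - cfg$vena_contracta_position), 10)
})

test_that("both time-search strategies agree on clean recordings", {
  cfg <- quiet_config()
  cfg$n_samples <- 8000L
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  avg <- ensemble_average(rec, segment_cycles(rec))
  m1 <- extract_metrics(avg, time_search = "peak-instant")
  m2 <- extract_metrics(avg, time_search = "all-instants")
  expect_rel_equal(m2$peak_drop, m1$peak_drop, 0.01)
})

test_that("constant-flow extraction time-averages and reports no peak-to-peak", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("constant", 250))
  m <- extract_metrics_constant_flow(denoise(rec))
  expect_true(is.na(m$peak_to_peak_drop))
  expect_rel_equal(m$peak_drop, rec$ground_truth$true_peak_drop, 0.02)
  # pulsatile recordings must take the pulsatile path
  recp <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  expect_error(extract_metrics_constant_flow(recp), "pulsatile path")
})

test_that("constant-flow extraction is insensitive to default-amplitude noise", {
  cfgq <- quiet_config()
  cfgn <- small_config(reflection_coefficient = 0)
  mq <- analyze_recording(simulate_recording(cfgq, flow_condition("constant", 250)))
  mn <- analyze_recording(simulate_recording(cfgn, flow_condition("constant", 250)))
  expect_rel_equal(mn$peak_drop, mq$peak_drop, 0.02)
})
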