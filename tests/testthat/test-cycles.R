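test_that("a 50,000-sample 10 kHz recording at 75 bpm yields 6 complete cycles", {
  # 5 s / 0.8 s = 6.25, so 6 complete cycles
  cfg <- quiet_config(sampling_rate = 10000, n_samples = 50000L)
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  cycles <- segment_cycles(rec)
  expect_equal(nrow(cycles), 6L)
  expect_true(all(cycles[, "end"] - cycles[, "start"] + 1L == 8000L))
})

test_that("recordings shorter than two cycles are rejected with an explicit message", {
  cfg <- quiet_config(n_samples = 3200L)  # exactly one cycle at 4 kHz
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  expect_error(segment_cycles(rec), "fewer than 2 cycles")
  cfgc <- quiet_config()
  expect_error(segment_cycles(simulate_recording(cfgc, flow_condition("constant", 100))),
               "pulsatile")
})

test_that("cycle count is invariant to a modest phase shift of the recording", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  n0 <- nrow(segment_cycles(rec))
  shifted <- rec
  # shift so the first upstroke lands shortly after the recording start
  k <- 3000
  shifted$pressures <- rbind(rec$pressures[(k + 1):nrow(rec$pressures), ],
                             rec$pressures[1:k, ])
  expect_equal(nrow(segment_cycles(shifted)), n0)
})

test_that("ensemble averaging of identical cycles returns the cycle with zero variance", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  cycles <- segment_cycles(rec)
  avg <- ensemble_average(rec, cycles)
  one <- rec$pressures[cycles[1, "start"]:cycles[1, "end"], ]
  expect_equal(avg$pressures, one, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(avg$beat_variance, rep(0, 8), tolerance = 1e-20)
  expect_equal(avg$n_cycles_used, nrow(cycles))
  expect_equal(max(avg$phase_time), (3200 - 1) / 4000)
})

test_that("averaging k noisy cycles shrinks the residual like sigma over sqrt(k)", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  clean_cycles <- segment_cycles(rec)
  k <- nrow(clean_cycles)
  sigma <- 0.5
  reps <- 40
  set.seed(99)
  resid_sd <- replicate(reps, {
    noisy <- rec
    noisy$pressures <- rec$pressures + matrix(rnorm(length(rec$pressures), sd = sigma),
                                              nrow = nrow(rec$pressures))
    avg <- ensemble_average(noisy, clean_cycles)
    one <- rec$pressures[clean_cycles[1, "start"]:clean_cycles[1, "end"], 1]
    sd(avg$pressures[, 1] - one)
  })
  expect_rel_equal(mean(resid_sd), sigma / sqrt(k), 0.05)
})

test_that("two-cycle averages are plain means and ragged cycles are rejected", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  cycles <- segment_cycles(rec)[1:2, ]
  avg <- ensemble_average(rec, cycles)
  a <- rec$pressures[cycles[1, "start"], 3]
  b <- rec$pressures[cycles[2, "start"], 3]
  expect_equal(avg$pressures[1, 3], (a + b) / 2, tolerance = 1e-12)

  bad <- cycles
  bad[2, "end"] <- bad[2, "end"] - 5L
  expect_error(ensemble_average(rec, bad), "inconsistent cycle lengths")
  expect_error(ensemble_average(rec, cycles[1, , drop = FALSE]), "at least 2")
})
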