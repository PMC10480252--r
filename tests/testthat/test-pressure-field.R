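test_that("simplified Bernoulli relation gives the clinical values", {
  expect_equal(bernoulli_drop(2.5), 25)
  expect_equal(bernoulli_drop(0), 0)
  expect_equal(bernoulli_drop(1), 4)
  expect_error(bernoulli_drop(-0.1), "non-negative")
})

test_that("constant flow through EOA 1.018 cm^2 yields the hand-computed vena-contracta drop", {
  # v = Q/EOA = 250/1.018 cm/s = 2.456 m/s; 4 v^2 = 24.13 mmHg
  cfg <- quiet_config(inertial_coefficient = 0)
  q <- generate_flow_waveform(flow_condition("constant", 250), 4000, 1000)
  field <- pressure_field(q, cfg)
  expect_equal(field$ground_truth$true_peak_drop, 4 * (250 / 1.018 / 100)^2,
               tolerance = 1e-12)
  expect_equal(field$ground_truth$true_peak_drop, 24.1, tolerance = 2e-3)
})

test_that("quasi-steady vena-contracta drop equals 4 (Q/EOA)^2 at every instant", {
  cfg <- quiet_config(inertial_coefficient = 0)
  q <- generate_flow_waveform(flow_condition("pulsatile", 250, 75), 4000, 6400,
                              cfg$systole_fraction, cfg$upstroke_fraction)
  field <- pressure_field(q, cfg)
  # channel 2 (+15 mm) lies inside the jet-core plateau: full drop applies
  pulse <- cfg$pulse_amplitude * q / cfg$pulse_reference_flow
  drop_ch2 <- cfg$upstream_baseline_pressure + pulse - field$pressures[, 2]
  expect_equal(drop_ch2, 4 * (q / cfg$valve_eoa / 100)^2, tolerance = 1e-10)
})

test_that("net fraction follows the orifice recovery law and r = 0.5 halves the drop", {
  cfg <- quiet_config(inertial_coefficient = 0)
  cfg <- set_orifice_ratio(cfg, 0.5)
  q <- generate_flow_waveform(flow_condition("constant", 250), 4000, 1000)
  field <- pressure_field(q, cfg)
  gt <- field$ground_truth
  expect_equal(gt$true_net_drop, 0.5 * gt$true_peak_drop, tolerance = 1e-12)

  # recovery bound: net/peak in [0.5, 1] across the full orifice range
  r <- seq(0.01, 0.99, by = 0.01)
  f <- recovery_fraction(r)
  expect_true(all(f >= 0.5 & f <= 1))
  expect_equal(min(f), 0.5, tolerance = 1e-6)
})

test_that("zero flow leaves every channel at baseline pressure", {
  cfg <- quiet_config()
  q <- rep(0, 1000)
  field <- pressure_field(q, cfg)
  expect_true(all(field$pressures == cfg$upstream_baseline_pressure))
})

test_that("the drop recovers spatially: +200 mm and +500 mm agree within 1 percent", {
  cfg <- quiet_config(inertial_coefficient = 0)
  q <- generate_flow_waveform(flow_condition("constant", 250), 4000, 100)
  p <- pressure_field(q, cfg)$pressures
  drop200 <- cfg$upstream_baseline_pressure + cfg$pulse_amplitude - p[1, 7]
  drop500 <- cfg$upstream_baseline_pressure + cfg$pulse_amplitude - p[1, 8]
  expect_lt(abs(drop200 / drop500 - 1), 0.01)
})

test_that("ground-truth peak drop increases strictly with peak flow", {
  cfg <- quiet_config()
  peaks <- sapply(c(100, 150, 200, 250), function(pf) {
    q <- generate_flow_waveform(flow_condition("pulsatile", pf, 75), 4000, 6400,
                                cfg$systole_fraction, cfg$upstroke_fraction)
    pressure_field(q, cfg)$ground_truth$true_peak_drop
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("a non-stenotic EOA is rejected", {
  expect_error(phantom_config(valve_eoa = 9), "tube cross-section")
  expect_error(recovery_fraction(0), "in \\(0, 1\\)")
})
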