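test_that("zero noise amplitudes give the identity", {
  cfg <- quiet_config()
  q <- generate_flow_waveform(flow_condition("pulsatile", 250, 75), 4000, 8000,
                              cfg$systole_fraction, cfg$upstroke_fraction)
  p <- pressure_field(q, cfg)$pressures
  expect_identical(add_noise(p, q, cfg, "pulsatile", seed = 1), p)
})

test_that("noise is strongest at the jet ports (channels 2-3) and weakest far downstream", {
  cfg <- small_config()
  cond <- flow_condition("pulsatile", 250, 75)
  q <- generate_flow_waveform(cond, cfg$sampling_rate, 20000,
                              cfg$systole_fraction, cfg$upstroke_fraction)
  clean <- pressure_field(q, cfg)$pressures
  cfg$recovery_noise_rel <- 0  # isolate the port-localised components
  noisy <- add_noise(clean, q, cfg, "pulsatile", seed = 7)
  resid_var <- apply(noisy - clean, 2, var)
  expect_gt(resid_var[2], resid_var[8])
  expect_gt(resid_var[3], resid_var[8])
})

test_that("constant flow amplifies jet turbulence noise by the configured factor", {
  cfg <- small_config()
  n <- 20000
  qp <- generate_flow_waveform(flow_condition("pulsatile", 250, 75),
                               cfg$sampling_rate, n,
                               cfg$systole_fraction, cfg$upstroke_fraction)
  qc <- generate_flow_waveform(flow_condition("constant", 250),
                               cfg$sampling_rate, n)
  cfg$noise_broadband_sd <- 0       # isolate the turbulence component
  cfg$pump_artifact_amplitude <- 0
  cfg$recovery_noise_rel <- 0
  clean_p <- pressure_field(qp, cfg)$pressures
  clean_c <- pressure_field(qc, cfg)$pressures
  vp <- var(add_noise(clean_p, qp, cfg, "pulsatile", seed = 3)[, 2] - clean_p[, 2])
  vc <- var(add_noise(clean_c, qc, cfg, "constant", seed = 3)[, 2] - clean_c[, 2])
  # variance ratio oracle: sd scales with factor * (v/vref)^2, so
  # var ratio = factor^2 * n / sum(q^4) with q the normalised pulsatile flow
  expected <- cfg$constant_flow_noise_factor^2 * n / sum((qp / 250)^4)
  expect_rel_equal(vc / vp, expected, 0.1)
})

test_that("noise is reproducible under a fixed seed", {
  cfg <- small_config()
  q <- generate_flow_waveform(flow_condition("pulsatile", 200, 75), 4000, 8000,
                              cfg$systole_fraction, cfg$upstroke_fraction)
  p <- pressure_field(q, cfg)$pressures
  expect_identical(add_noise(p, q, cfg, "pulsatile", seed = 11),
                   add_noise(p, q, cfg, "pulsatile", seed = 11))
})

test_that("pump artifact bursts sit at peak dQ/dt and peak flow and only in pulsatile mode", {
  cfg <- quiet_config(pump_artifact_amplitude = 1)
  q <- generate_flow_waveform(flow_condition("pulsatile", 250, 75), 4000, 6400,
                              cfg$systole_fraction, cfg$upstroke_fraction)
  p <- pressure_field(q, cfg)$pressures
  out <- add_noise(p, q, cfg, "pulsatile", seed = 1)
  resid <- out[, 1] - p[, 1]
  active <- which(abs(resid) > 0.05)
  expect_gt(length(active), 0)
  t_up <- 0.3 * 0.35 * 0.8
  centres <- c(t_up / 2, t_up)  # peak dQ/dt, then peak flow, each cycle
  t_active <- ((active - 1) / 4000) %% 0.8
  dist <- sapply(t_active, function(t) min(abs(t - centres)))
  expect_lt(max(dist), 0.025)  # all bursts within the 4-sigma envelope
})
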