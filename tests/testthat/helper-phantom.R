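# Shared fixtures: small, fast configurations of the virtual phantom.

config_with <- function(defaults, ...) {
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}

# Noise-free, reflection-free phantom at reduced acquisition scale
# (4 kHz x 2.5 s = 3 complete cycles at 75 bpm).
quiet_config <- function(...) {
  config_with(list(sampling_rate = 4000, n_samples = 10000L,
                   noise_broadband_sd = 0, turbulence_noise_amplitude = 0,
                   pump_artifact_amplitude = 0, recovery_noise_rel = 0,
                   reflection_coefficient = 0), ...)
}

# Same acquisition scale with the default noise and reflection settings.
small_config <- function(...) {
  config_with(list(sampling_rate = 4000, n_samples = 10000L), ...)
}

# Harness-scale config: 5 s at 4 kHz = 6 complete cycles, as in the full
# 50,000-sample acquisition.
harness_config <- function(...) {
  config_with(list(sampling_rate = 4000, n_samples = 20000L), ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
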