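#' Deterministic miniature recordings for fast tests and examples
#'
#' Small recordings (2 kHz, 2 s, i.e. 2 complete cycles at 75 bpm) built
#' from the default phantom with fixed seeds:
#' \describe{
#'   \item{"clean"}{pulsatile 250 ml/s, zero noise, no reflection;
#'     pipeline metrics match the generator ground truth closely.}
#'   \item{"noisy"}{pulsatile 250 ml/s with default noise, artifacts and
#'     reflection.}
#'   \item{"reflected"}{pulsatile 250 ml/s, zero noise, reflection
#'     coefficient 0.3.}
#'   \item{"constant"}{constant 250 ml/s with default noise; no cycle
#'     structure, peak-to-peak undefined.}
#' }
#'
#' @param name Fixture name.
#' @return A `sensor_recording`.
#' @examples
#' rec <- make_fixture("clean")
#' analyze_recording(rec)
#' @export
make_fixture <- function(name = c("clean", "noisy", "reflected", "constant")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("clean", "noisy", "reflected", "constant")) {
    stop("unknown fixture name: ", paste(name, collapse = ", "), call. = FALSE)
  }
  base <- list(sampling_rate = 2000, n_samples = 4000L)
  quiet <- list(noise_broadband_sd = 0, turbulence_noise_amplitude = 0,
                pump_artifact_amplitude = 0, recovery_noise_rel = 0)
  cfg <- switch(name,
    clean = do.call(phantom_config,
                    c(base, quiet, list(reflection_coefficient = 0,
                                        rng_seed = 101L))),
    noisy = do.call(phantom_config, c(base, list(rng_seed = 102L))),
    reflected = do.call(phantom_config,
                        c(base, quiet, list(reflection_coefficient = 0.3,
                                            rng_seed = 103L))),
    constant = do.call(phantom_config, c(base, list(rng_seed = 104L))))
  cond <- if (name == "constant") {
    flow_condition("constant", peak_flow = 250)
  } else {
    flow_condition("pulsatile", peak_flow = 250, heart_rate = 75)
  }
  simulate_recording(cfg, cond, provenance = list(fixture = name))
}
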