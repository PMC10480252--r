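#' Simulate an 8-channel pressure recording
#'
#' Runs the full generator chain: flow waveform -> noiseless pressure
#' field (with ground truth) -> reflected wave -> noise and pump
#' artifacts -> reference-transducer zero offset. The result carries the
#' sensor array, the flow condition, the generator ground truth and
#' free-text provenance, and is the input to the analysis pipeline.
#'
#' @param config A [phantom_config()]. Its `rng_seed` seeds the noise.
#' @param condition A [flow_condition()].
#' @param provenance Optional named list of free-text metadata (e.g.
#'   handling condition, session).
#' @return An object of class `sensor_recording`: `time` (s), `pressures`
#'   (samples x channels, mmHg), `sensor_array`, `condition`,
#'   `ground_truth`, `provenance`, `sampling_rate`, `seed`.
#' @examples
#' cfg <- phantom_config(sampling_rate = 2000, n_samples = 3200)
#' rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
#' rec
#' @export
simulate_recording <- function(config, condition, provenance = list()) {
  validate_phantom_config(config)
  stopifnot(inherits(condition, "flow_condition"))
  flow <- generate_flow_waveform(condition, config$sampling_rate,
                                 config$n_samples,
                                 systole_fraction = config$systole_fraction,
                                 upstroke_fraction = config$upstroke_fraction)
  field <- pressure_field(flow, config)
  pressures <- add_wave_reflection(field$pressures, config, mode = condition$mode)
  pressures <- add_noise(pressures, flow, config, mode = condition$mode,
                         seed = config$rng_seed)
  if (config$reference_zero_offset != 0) {
    pressures[, 1] <- pressures[, 1] + config$reference_zero_offset
  }
  structure(
    list(time = field$time,
         pressures = pressures,
         sensor_array = config$sensor_array,
         condition = condition,
         ground_truth = field$ground_truth,
         provenance = provenance,
         sampling_rate = config$sampling_rate,
         seed = config$rng_seed),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d samples x %d channels @ %g Hz\n",
              nrow(x$pressures), ncol(x$pressures), x$sampling_rate))
  print(x$condition)
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: peak %.2f mmHg, net %.2f mmHg at t = %.3f s\n",
                x$ground_truth$true_peak_drop, x$ground_truth$true_net_drop,
                x$ground_truth$true_peak_instant))
  }
  if (length(x$provenance)) {
    cat("  provenance: ",
        paste(names(x$provenance), unlist(x$provenance),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
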