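#' Add a reflected (backward-travelling) pressure wave
#'
#' The tube end is an impedance mismatch: a fraction `Gamma` of the forward
#' pressure wave is reflected and travels back up the tube. At axial
#' position `x` the reflected component is the forward AC pressure delayed
#' by the round trip to the reflection site, `tau(x) = 2 (site - x) / c`,
#' scaled by `Gamma`. Superposition of the forward and backward waves
#' augments distal pressures and shifts the instants of their temporal
#' maxima - the mechanism that confounds the peak-to-peak pressure-drop
#' metric while leaving same-instant channel differences nearly untouched.
#'
#' The forward wave is treated as spatially instantaneous (long-wavelength
#' limit). The delay is applied as a zero-padded shift of the AC component
#' (pressure minus the diastolic baseline); for recordings that start at a
#' cycle onset this equals the periodic steady state, because the pre-
#' arrival history falls in diastole where the AC pressure vanishes.
#' Constant flow carries no travelling transient, so the matrix is
#' returned unchanged in constant mode.
#'
#' @param pressures Pressure matrix, samples x channels, mmHg.
#' @param config A [phantom_config()]; uses `reflection_coefficient`,
#'   `reflection_site`, `wave_speed`, `upstream_baseline_pressure`,
#'   `sampling_rate` and the sensor positions.
#' @param mode `"pulsatile"` or `"constant"`.
#' @return The pressure matrix with the reflected wave added.
#' @export
add_wave_reflection <- function(pressures, config, mode = "pulsatile") {
  validate_phantom_config(config)
  gamma <- config$reflection_coefficient
  if (gamma == 0 || mode == "constant") {
    return(pressures)
  }
  positions <- config$sensor_array$positions
  if (ncol(pressures) != length(positions)) {
    stop("channel count does not match sensor array", call. = FALSE)
  }
  c_mm_s <- config$wave_speed * 1000  # m/s -> mm/s
  out <- pressures
  for (j in seq_along(positions)) {
    delay_s <- 2 * (config$reflection_site - positions[j]) / c_mm_s
    if (delay_s < 0) {
      stop("sensor beyond the reflection site", call. = FALSE)
    }
    k <- as.integer(round(delay_s * config$sampling_rate))
    ac <- pressures[, j] - config$upstream_baseline_pressure
    out[, j] <- pressures[, j] + gamma * delay_shift(ac, k)
  }
  out
}

# Delay a signal by k samples, padding with zeros: before the first
# round trip completes there is no reflected wave. With recordings that
# start at a cycle onset the padded region coincides with late diastole of
# the (quiescent) previous cycle, where the AC pressure is zero anyway, so
# this equals the periodic steady state.
delay_shift <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k >= n) return(numeric(n))
  c(numeric(k), x[1:(n - k)])
}
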