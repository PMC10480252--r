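#' Add measurement noise and pump artifacts
#'
#' Three noise components, matching the phenomenology of wall-port pressure
#' sensing in a mock loop:
#' \itemize{
#'   \item broadband Gaussian sensor noise (`noise_broadband_sd`) on every
#'     channel;
#'   \item turbulence noise from the jet, strongest at the ports closest to
#'     the valve: sd `turbulence_noise_amplitude *
#'     exp(-|x - x_vc| / turbulence_decay_length) * (v(t)/v_ref)^2`,
#'     multiplied by `constant_flow_noise_factor` under constant flow
#'     (steady flow gives turbulence time to fully develop, and the valve
#'     leaflets flutter);
#'   \item a slow coherent oscillation of the recovered pressure: the
#'     jet-breakdown region flaps at sub-Hz timescales (correlation time
#'     `recovery_noise_corr_time`), modulating the recovered pressure
#'     component by a relative amplitude `recovery_noise_rel`; it affects
#'     the recovery-zone ports only and survives ensemble averaging in
#'     part;
#'   \item a pump artifact (pulsatile only): a short high-frequency burst,
#'     identical on all channels, centred at the instants of peak dQ/dt and
#'     peak flow of each cycle.
#' }
#' All amplitudes may be zero, in which case the matrix passes through
#' unchanged. Randomness is drawn from R's global RNG; seed it (or pass
#' `seed`) for reproducibility.
#'
#' @param pressures Pressure matrix, samples x channels, mmHg.
#' @param flow Flow trace, ml/s (drives the turbulence scaling and the
#'   artifact timing).
#' @param config A [phantom_config()].
#' @param mode `"pulsatile"` or `"constant"`.
#' @param seed Optional integer seed applied before drawing noise.
#' @return The noisy pressure matrix.
#' @export
add_noise <- function(pressures, flow, config, mode = "pulsatile", seed = NULL) {
  validate_phantom_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pressures)
  positions <- config$sensor_array$positions
  out <- pressures

  v <- (flow / config$valve_eoa) / 100  # m/s
  turb_gain <- (v / config$turbulence_reference_velocity)^2
  if (mode == "constant") {
    turb_gain <- turb_gain * config$constant_flow_noise_factor
  }
  for (j in seq_along(positions)) {
    sd_turb <- config$turbulence_noise_amplitude *
      exp(-abs(positions[j] - config$vena_contracta_position) /
            config$turbulence_decay_length) * turb_gain
    # Broadband sensor noise is white; turbulence/leaflet-flutter noise is
    # high-frequency (vortex shedding), modelled as first-differenced white
    # noise (spectrum ~ sin^2(pi f / fs), negligible power at cardiac
    # frequencies), each calibrated to the stated raw sd.
    if (config$noise_broadband_sd > 0) {
      out[, j] <- out[, j] + rnorm(n, sd = config$noise_broadband_sd)
    }
    if (any(sd_turb > 0)) {
      hf <- diff(rnorm(n + 1)) / sqrt(2)
      out[, j] <- out[, j] + hf * sd_turb
    }
  }

  if (config$recovery_noise_rel > 0 && any(flow > 0)) {
    # AR(1) process, unit stationary sd, shared across channels: one
    # physical jet state modulates the whole recovery zone coherently.
    phi <- exp(-1 / (config$sampling_rate * config$recovery_noise_corr_time))
    innov <- rnorm(n, sd = sqrt(1 - phi^2))
    slow <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    vc <- vena_contracta_drop(flow, config)
    shape <- axial_drop_shape(positions, config)
    x_end <- config$vena_contracta_position + config$jet_core_half_width
    for (j in seq_along(positions)) {
      if (positions[j] <= x_end) next
      recovered <- vc * (1 - shape[j])  # pressure regained at this port
      out[, j] <- out[, j] +
        config$recovery_noise_rel * slow * recovered
    }
  }

  if (mode == "pulsatile" && config$pump_artifact_amplitude > 0 && any(flow > 0)) {
    burst <- pump_artifact_trace(flow, config)
    out <- out + burst  # recycled column-wise: identical on all channels
  }
  out
}

# Deterministic high-frequency bursts at the instants of peak dQ/dt and
# peak flow (Gaussian-windowed sinusoid, sd 5 ms), identical on all
# channels: the pump, not the sensors, is the source.
pump_artifact_trace <- function(flow, config) {
  fs <- config$sampling_rate
  n <- length(flow)
  t <- (seq_len(n) - 1) / fs
  dq <- finite_diff(flow, fs)
  centres <- c(local_maxima(dq, frac = 0.5), local_maxima(flow, frac = 0.9))
  burst <- numeric(n)
  sigma <- 0.005
  for (i0 in centres) {
    dt <- t - t[i0]
    keep <- abs(dt) < 4 * sigma
    burst[keep] <- burst[keep] + config$pump_artifact_amplitude *
      sin(2 * pi * config$pump_artifact_frequency * dt[keep]) *
      exp(-dt[keep]^2 / (2 * sigma^2))
  }
  burst
}

# Indices of strict local maxima exceeding frac * global max, separated by
# at least min_sep samples (keeps one representative per event).
local_maxima <- function(x, frac = 0.5, min_sep = 16L) {
  n <- length(x)
  if (n < 3 || max(x) <= 0) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= frac * max(x)]
  if (length(cand) == 0) return(cand)
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
  }
  keep
}
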