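#' Noiseless 1-D pressure field of the virtual phantom
#'
#' Maps a flow trace onto pressures at the sensor positions. At each
#' instant the vena-contracta drop is
#' `dP_vc(t) = 4 v(t)^2 + K rho L_eff dv/dt` (v = Q/EOA in m/s; the
#' inertial term vanishes for constant flow and in the quasi-steady
#' configuration `K = 0`). Axially, the drop ramps up smoothly from the
#' valve plane, holds at `dP_vc` across the jet core
#' (`vena_contracta_position` +/- `jet_core_half_width`) and relaxes
#' exponentially (length `recovery_length`) toward the net drop
#' `dP_net(t) = dP_vc(t) * (1 - 2 r (1 - r) * recovery_efficiency)`,
#' `r = EOA / A_tube`.
#' Upstream ports see no drop. All ports additionally carry the common
#' pump pulse pressure `pulse_amplitude * Q(t) / pulse_reference_flow`
#' on top of the diastolic baseline.
#'
#' @param flow Flow trace, ml/s (from [generate_flow_waveform()]).
#' @param config A [phantom_config()].
#' @return A list with `pressures` (matrix, samples x channels, mmHg),
#'   `time` (s) and `ground_truth` (class `ground_truth`: `true_peak_drop`,
#'   `true_net_drop`, `true_peak_instant`, `true_peak_location`,
#'   `flow_waveform`).
#' @examples
#' cfg <- phantom_config(sampling_rate = 1000, n_samples = 800)
#' q <- generate_flow_waveform(flow_condition("constant", 250), 1000, 800)
#' field <- pressure_field(q, cfg)
#' field$ground_truth$true_peak_drop # ~24.1 mmHg at EOA 1.018 cm^2
#' @export
pressure_field <- function(flow, config) {
  validate_phantom_config(config)
  if (length(flow) < 2) stop("`flow` must have at least 2 samples", call. = FALSE)
  if (any(flow < 0)) stop("`flow` must be non-negative", call. = FALSE)
  fs <- config$sampling_rate
  time <- (seq_along(flow) - 1) / fs

  vc <- vena_contracta_drop(flow, config)
  f_net <- net_fraction(config)
  shape <- axial_drop_shape(config$sensor_array$positions, config)

  pulse <- config$pulse_amplitude * flow / config$pulse_reference_flow
  # P(x, t) = baseline + pulse(t) - dP_vc(t) * shape(x); shape folds in the
  # ramp, jet-core plateau and exponential recovery toward f_net.
  base <- config$upstream_baseline_pressure + pulse
  pressures <- outer(rep(1, length(flow)), numeric(n_channels(config$sensor_array)))
  for (j in seq_len(ncol(pressures))) {
    pressures[, j] <- base - vc * shape[j]
  }
  colnames(pressures) <- paste0("ch", config$sensor_array$channel_ids)

  i_peak <- which.max(vc)
  gt <- structure(
    list(true_peak_drop = vc[i_peak],
         true_net_drop = f_net * vc[i_peak],
         true_peak_instant = time[i_peak],
         true_peak_location = config$vena_contracta_position,
         flow_waveform = flow),
    class = "ground_truth"
  )
  list(pressures = pressures, time = time, ground_truth = gt)
}

# Instantaneous vena-contracta drop, mmHg: simplified Bernoulli plus the
# unsteady inertial term K * rho * L_eff * dv/dt (SI, converted to mmHg).
vena_contracta_drop <- function(flow, config) {
  v <- (flow / config$valve_eoa) / 100  # (ml/s)/cm^2 = cm/s -> m/s
  drop <- bernoulli_drop(v)
  if (config$inertial_coefficient != 0) {
    dvdt <- finite_diff(v, config$sampling_rate)
    rho_si <- config$fluid_density * 1000    # g/cm^3 -> kg/m^3
    l_si <- config$effective_length / 1000   # mm -> m
    drop <- drop + config$inertial_coefficient * rho_si * l_si * dvdt * MMHG_PER_PA
  }
  drop
}

# Central-difference time derivative (one-sided at the ends).
finite_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Unrecovered (net) fraction of the vena-contracta drop for a config,
# including the recovery-efficiency factor.
net_fraction <- function(config) {
  r <- orifice_ratio(config)
  1 - 2 * r * (1 - r) * config$recovery_efficiency
}

# Dimensionless axial profile of the pressure drop: 0 upstream, sin^2 ramp
# from the valve plane to the jet core, 1 across the core, then exponential
# relaxation toward the unrecovered fraction f_net.
axial_drop_shape <- function(x, config) {
  f_net <- net_fraction(config)
  x_start <- config$vena_contracta_position - config$jet_core_half_width
  x_end <- config$vena_contracta_position + config$jet_core_half_width
  if (x_start <= 0) stop("jet core must begin downstream of the valve plane",
                         call. = FALSE)
  shape <- numeric(length(x))
  ramp <- x > 0 & x < x_start
  shape[ramp] <- sin(pi * x[ramp] / (2 * x_start))^2
  shape[x >= x_start & x <= x_end] <- 1
  rec <- x > x_end
  shape[rec] <- f_net + (1 - f_net) * exp(-(x[rec] - x_end) / config$recovery_length)
  shape
}
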