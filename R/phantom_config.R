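#' Virtual phantom configuration
#'
#' Collects the geometry, valve, pressure-recovery, wave-reflection, noise
#' and acquisition parameters of the virtual straight-tube phantom. The
#' defaults describe a 32-mm ID silicone tube carrying a blood-mimicking
#' fluid (density 1.119 g/cm^3, viscosity 4.83e-3 Pa s) with a healthy
#' valve whose effective orifice area (1.018 cm^2) yields the calibrated
#' 24.1 mmHg simplified-Bernoulli drop at 250 ml/s.
#'
#' The pressure model is 1-D and parametric: at each instant the
#' vena-contracta drop is `4 v^2` (v = Q/EOA, m/s) plus an optional
#' inertial term `K rho L_eff dv/dt`; the drop holds across a jet-core
#' plateau (`vena_contracta_position` +/- `jet_core_half_width`), ramps up
#' smoothly from the valve plane, and relaxes exponentially downstream
#' (length `recovery_length`) toward the net drop
#' `dP_net = dP_vc (1 - 2 r (1 - r))`, `r = EOA / A_tube`.
#'
#' @param sensor_array A [sensor_array()].
#' @param tube_internal_diameter Tube internal diameter, mm.
#' @param tube_length Tube length downstream of the valve, mm (reflection site).
#' @param fluid_density Fluid density, g/cm^3.
#' @param fluid_viscosity Dynamic viscosity, Pa s (metadata; the 1-D model
#'   carries no explicit viscous loss term).
#' @param valve_eoa Valve effective orifice area, cm^2; must be positive and
#'   smaller than the tube cross-section.
#' @param vena_contracta_position Axial position of the vena contracta, mm.
#' @param jet_core_half_width Half-length of the jet-core plateau over which
#'   the full vena-contracta drop applies, mm.
#' @param recovery_length Exponential length scale of downstream pressure
#'   recovery, mm. The default (35 mm) completes >= 99 percent of the
#'   recovery by the +200 mm port.
#' @param recovery_efficiency Fraction of the ideal orifice recovery
#'   actually achieved (default 1). Jet angulation, wall deformation and
#'   flow oscillation make the recovered pressure imperfect and
#'   mount-dependent; the net drop becomes
#'   `dP_vc (1 - 2 r (1 - r) * recovery_efficiency)`.
#' @param upstream_baseline_pressure Diastolic baseline pressure, mmHg.
#' @param pulse_amplitude Upstream pulse-pressure amplitude at
#'   `pulse_reference_flow`, mmHg; the pulse scales linearly with flow.
#' @param pulse_reference_flow Reference peak flow for `pulse_amplitude`, ml/s.
#' @param systole_fraction Fraction of the cycle occupied by systole.
#' @param upstroke_fraction Fraction of systole occupied by the upstroke.
#' @param inertial_coefficient Dimensionless gain `K` on the unsteady
#'   (inertial) term; 0 gives the quasi-steady Bernoulli regime.
#' @param effective_length Effective inertial length `L_eff`, mm.
#' @param reflection_coefficient Reflection coefficient at the tube end,
#'   dimensionless in `[0, 1)`.
#' @param reflection_site Axial position of the reflecting tube end, mm.
#' @param wave_speed Pressure wave speed in the tube, m/s.
#' @param noise_broadband_sd Broadband Gaussian sensor noise sd, mmHg.
#' @param turbulence_noise_amplitude Turbulence noise sd at the vena
#'   contracta and reference velocity, mmHg.
#' @param turbulence_decay_length Axial e-folding length of turbulence
#'   noise, mm.
#' @param turbulence_reference_velocity Reference jet velocity for the
#'   turbulence noise scaling, m/s.
#' @param constant_flow_noise_factor Multiplier on turbulence noise in
#'   constant-flow mode (fully developed turbulence).
#' @param recovery_noise_rel Relative amplitude of the slow oscillation of
#'   the recovered pressure component downstream of the jet (coherent
#'   jet-breakdown flapping; correlation time
#'   `recovery_noise_corr_time`). Ensemble averaging only partially
#'   suppresses it, which is what makes the distal (net, peak-to-peak)
#'   metrics noisier than the jet-core peak metric.
#' @param recovery_noise_corr_time Correlation time of that oscillation, s.
#' @param pump_artifact_amplitude Amplitude of the localized high-frequency
#'   pump artifact, mmHg (pulsatile only).
#' @param pump_artifact_frequency Artifact carrier frequency, Hz.
#' @param reference_zero_offset Additive zero error on the reference
#'   transducer (channel 1), mmHg; default 0. Used by the "zeroing" variant
#'   of the day-2 bias perturbation.
#' @param sampling_rate Sampling rate, Hz.
#' @param n_samples Samples per channel.
#' @param rng_seed Integer seed consumed by the stochastic components.
#' @return An object of class `phantom_config`.
#' @examples
#' cfg <- phantom_config()
#' tube_area(cfg)     # cm^2
#' orifice_ratio(cfg) # EOA / tube area
#' @export
phantom_config <- function(sensor_array = flowphantom::sensor_array(),
                           tube_internal_diameter = 32,
                           tube_length = 600,
                           fluid_density = 1.119,
                           fluid_viscosity = 4.83e-3,
                           valve_eoa = 1.018,
                           vena_contracta_position = 25,
                           jet_core_half_width = 13,
                           recovery_length = 35,
                           recovery_efficiency = 1,
                           upstream_baseline_pressure = 60,
                           pulse_amplitude = 40,
                           pulse_reference_flow = 250,
                           systole_fraction = 0.35,
                           upstroke_fraction = 0.3,
                           inertial_coefficient = 1,
                           effective_length = 30,
                           reflection_coefficient = 0.4,
                           reflection_site = tube_length,
                           wave_speed = 8,
                           noise_broadband_sd = 0.3,
                           turbulence_noise_amplitude = 1.5,
                           turbulence_decay_length = 30,
                           turbulence_reference_velocity = 2.5,
                           constant_flow_noise_factor = 3,
                           recovery_noise_rel = 0.5,
                           recovery_noise_corr_time = 0.8,
                           pump_artifact_amplitude = 1,
                           pump_artifact_frequency = 120,
                           reference_zero_offset = 0,
                           sampling_rate = 10000,
                           n_samples = 50000,
                           rng_seed = 1L) {
  cfg <- structure(
    list(sensor_array = sensor_array,
         tube_internal_diameter = tube_internal_diameter,
         tube_length = tube_length,
         fluid_density = fluid_density,
         fluid_viscosity = fluid_viscosity,
         valve_eoa = valve_eoa,
         vena_contracta_position = vena_contracta_position,
         jet_core_half_width = jet_core_half_width,
         recovery_length = recovery_length,
         recovery_efficiency = recovery_efficiency,
         upstream_baseline_pressure = upstream_baseline_pressure,
         pulse_amplitude = pulse_amplitude,
         pulse_reference_flow = pulse_reference_flow,
         systole_fraction = systole_fraction,
         upstroke_fraction = upstroke_fraction,
         inertial_coefficient = inertial_coefficient,
         effective_length = effective_length,
         reflection_coefficient = reflection_coefficient,
         reflection_site = reflection_site,
         wave_speed = wave_speed,
         noise_broadband_sd = noise_broadband_sd,
         turbulence_noise_amplitude = turbulence_noise_amplitude,
         turbulence_decay_length = turbulence_decay_length,
         turbulence_reference_velocity = turbulence_reference_velocity,
         constant_flow_noise_factor = constant_flow_noise_factor,
         recovery_noise_rel = recovery_noise_rel,
         recovery_noise_corr_time = recovery_noise_corr_time,
         pump_artifact_amplitude = pump_artifact_amplitude,
         pump_artifact_frequency = pump_artifact_frequency,
         reference_zero_offset = reference_zero_offset,
         sampling_rate = sampling_rate,
         n_samples = as.integer(n_samples),
         rng_seed = as.integer(rng_seed)),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (!inherits(cfg$sensor_array, "sensor_array")) {
    stop("`sensor_array` must be a sensor_array object", call. = FALSE)
  }
  if (cfg$valve_eoa <= 0) {
    stop("`valve_eoa` must be positive", call. = FALSE)
  }
  if (cfg$valve_eoa >= tube_area(cfg)) {
    stop("`valve_eoa` must be smaller than the tube cross-section ",
         "(no stenosis to model)", call. = FALSE)
  }
  if (cfg$reflection_coefficient < 0 || cfg$reflection_coefficient >= 1) {
    stop("`reflection_coefficient` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$recovery_length <= 0 || cfg$wave_speed <= 0 ||
      cfg$sampling_rate <= 0 || cfg$n_samples < 2) {
    stop("geometry/acquisition parameters must be positive", call. = FALSE)
  }
  if (cfg$recovery_efficiency <= 0 || cfg$recovery_efficiency > 1.2) {
    stop("`recovery_efficiency` must lie in (0, 1.2]", call. = FALSE)
  }
  if (cfg$systole_fraction <= 0 || cfg$systole_fraction >= 1 ||
      cfg$upstroke_fraction <= 0 || cfg$upstroke_fraction >= 1) {
    stop("`systole_fraction` and `upstroke_fraction` must lie in (0, 1)",
         call. = FALSE)
  }
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  tube: %g mm ID x %g mm; fluid %g g/cm^3\n",
              x$tube_internal_diameter, x$tube_length, x$fluid_density))
  cat(sprintf("  valve: EOA %g cm^2 (r = %.3f), vena contracta %+g mm\n",
              x$valve_eoa, orifice_ratio(x), x$vena_contracta_position))
  cat(sprintf("  reflection: Gamma %g at %+g mm, c = %g m/s\n",
              x$reflection_coefficient, x$reflection_site, x$wave_speed))
  cat(sprintf("  acquisition: %g Hz x %d samples, %d channels\n",
              x$sampling_rate, x$n_samples, n_channels(x$sensor_array)))
  invisible(x)
}

#' @rdname phantom_config
#' @param cfg A `phantom_config`.
#' @export
tube_area <- function(cfg) {
  d_cm <- cfg$tube_internal_diameter / 10
  pi * d_cm^2 / 4
}

#' @rdname phantom_config
#' @export
orifice_ratio <- function(cfg) {
  cfg$valve_eoa / tube_area(cfg)
}

#' Fraction of the vena-contracta drop that is not recovered downstream
#'
#' Standard orifice pressure-recovery relation: a stenosis with
#' orifice-to-tube area ratio `r` recovers part of the vena-contracta drop,
#' leaving a net (irreversible) drop `dP_net = dP_vc (1 - 2 r (1 - r))`.
#' The factor is minimal (0.5) at r = 0.5 and tends to 1 as r tends to 0
#' (no recovery for a pinhole jet) or 1 (no stenosis).
#'
#' @param r Orifice-to-tube area ratio in (0, 1). Vectorised.
#' @return Net-to-peak drop fraction in `[0.5, 1]`.
#' @examples
#' recovery_fraction(0.245) # 0.63, the regime of the reference experiments
#' @export
recovery_fraction <- function(r) {
  if (any(r <= 0 | r >= 1)) {
    stop("`r` must lie in (0, 1)", call. = FALSE)
  }
  1 - 2 * r * (1 - r)
}

#' Set the valve EOA from a target orifice ratio
#'
#' Convenience helper: returns a config whose `valve_eoa` equals
#' `r * tube_area(cfg)`.
#'
#' @param cfg A `phantom_config`.
#' @param r Target orifice-to-tube area ratio in (0, 1).
#' @return The modified `phantom_config`.
#' @export
set_orifice_ratio <- function(cfg, r) {
  if (r <= 0 || r >= 1) stop("`r` must lie in (0, 1)", call. = FALSE)
  cfg$valve_eoa <- r * tube_area(cfg)
  validate_phantom_config(cfg)
}
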