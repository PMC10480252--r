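#' Perturb a phantom configuration for a handling condition and session
#'
#' Emulates the between-run handling of the physical phantom in the
#' test-retest protocol. Condition 1 is the untouched baseline. Condition 2
#' (purge and refill, with the tubing lifted and repositioned) perturbs the
#' afterload and the distal coupling: baseline pressure and reflection
#' coefficient are jittered by `afterload_jitter`, and the coupling
#' parameters that the bench protocol cannot control tightly - pump pulse
#' amplitude, wave speed (trapped air changes tube compliance) and
#' reflection-site position (tubing repositioned) - by the larger
#' `coupling_jitter`. Condition 3 (dismantle, remove and
#' remount the same valve) additionally jitters the vena-contracta
#' position, the EOA (remount error) and the recovery efficiency (the
#' recovered pressure depends on jet angulation and wall behaviour, which
#' change with every remount). Condition 4 (mount a nominally identical
#' sister valve) additionally applies a valve-manufacture EOA offset.
#' Session B applies a systematic obstruction increase (`EOA *
#' session_b_eoa_factor`) on top, emulating the day-2 bias: either leaflet
#' degradation or a transducer zeroing error; the obstruction form is the
#' default, the zeroing form (an additive offset on the reference
#' transducer) is available via `session_b_mode`.
#'
#' Jitters are uniform on +/- the stated magnitude (relative, except the
#' vena-contracta position). Eight deviates are drawn in a fixed order
#' (baseline, reflection coefficient, pulse amplitude, wave speed,
#' reflection site, vena-contracta position, remount EOA, recovery
#' efficiency, valve EOA) regardless of condition, so a given seed yields the same perturbation
#' stream whichever condition consumes it.
#'
#' @param config Base [phantom_config()].
#' @param condition_label Handling condition, integer 1-4.
#' @param session `"A"` or `"B"`.
#' @param seed Optional integer seed applied before drawing jitters.
#' @param afterload_jitter Relative jitter on baseline pressure and
#'   reflection coefficient (conditions 2-4).
#' @param coupling_jitter Relative jitter on pulse amplitude, wave speed
#'   and reflection site (conditions 2-4).
#' @param position_jitter Absolute jitter on the vena-contracta position,
#'   mm (conditions 3-4).
#' @param remount_eoa_jitter Relative EOA jitter from valve remounting
#'   (conditions 3-4).
#' @param recovery_jitter Relative jitter on the recovery efficiency
#'   (conditions 3-4): remount-dependent jet angulation, wall deformation
#'   and oscillation change how much pressure is actually recovered at the
#'   distal ports.
#' @param valve_eoa_jitter Relative EOA offset from valve-to-valve
#'   manufacturing variability (condition 4).
#' @param session_b_eoa_factor Multiplier on EOA in session B.
#' @param session_b_mode `"obstruction"` (EOA reduction) or `"zeroing"`
#'   (additive offset of `session_b_zero_offset` mmHg on the reference
#'   transducer, channel 1).
#' @param session_b_zero_offset Zeroing offset used by the `"zeroing"` mode.
#' @return The perturbed `phantom_config`.
#' @export
apply_condition_perturbation <- function(config, condition_label, session,
                                         seed = NULL,
                                         afterload_jitter = 0.05,
                                         coupling_jitter = 0.25,
                                         position_jitter = 3,
                                         remount_eoa_jitter = 0.02,
                                         recovery_jitter = 0.15,
                                         valve_eoa_jitter = 0.03,
                                         session_b_eoa_factor = 0.96,
                                         session_b_mode = c("obstruction", "zeroing"),
                                         session_b_zero_offset = 1) {
  validate_phantom_config(config)
  session_b_mode <- match.arg(session_b_mode)
  if (!condition_label %in% 1:4) {
    stop("unknown condition label: ", condition_label, call. = FALSE)
  }
  if (!session %in% c("A", "B")) {
    stop("`session` must be \"A\" or \"B\"", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # fixed draw order: baseline, Gamma, pulse, wave speed, site, position,
  # remount EOA, recovery efficiency, valve EOA
  u <- runif(9, -1, 1)

  out <- config
  if (condition_label >= 2) {
    out$upstream_baseline_pressure <-
      out$upstream_baseline_pressure * (1 + afterload_jitter * u[1])
    out$reflection_coefficient <-
      min(out$reflection_coefficient * (1 + afterload_jitter * u[2]), 0.99)
    out$pulse_amplitude <- out$pulse_amplitude * (1 + coupling_jitter * u[3])
    out$wave_speed <- out$wave_speed * (1 + coupling_jitter * u[4])
    out$reflection_site <-
      max(out$reflection_site * (1 + coupling_jitter * u[5]),
          max(out$sensor_array$positions) + 20)
  }
  if (condition_label >= 3) {
    out$vena_contracta_position <-
      out$vena_contracta_position + position_jitter * u[6]
    out$valve_eoa <- out$valve_eoa * (1 + remount_eoa_jitter * u[7])
    out$recovery_efficiency <-
      min(out$recovery_efficiency * (1 + recovery_jitter * u[8]), 1.2)
  }
  if (condition_label == 4) {
    out$valve_eoa <- out$valve_eoa * (1 + valve_eoa_jitter * u[9])
  }
  if (session == "B") {
    if (session_b_mode == "obstruction") {
      out$valve_eoa <- out$valve_eoa * session_b_eoa_factor
    } else {
      out$reference_zero_offset <-
        out$reference_zero_offset + session_b_zero_offset
    }
  }
  validate_phantom_config(out)
}
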