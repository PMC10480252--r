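#' Instant of the peak pressure drop
#'
#' Identifies the phase instant at which the pressure difference between
#' the reference channel (before the valve) and the distal channel (after
#' pressure recovery; channel 7 rather than 8, whose trace is contaminated
#' by end-of-tube reflections) is maximal. Ties break to the earliest
#' instant.
#'
#' @param avg A `beat_averaged_tracing`.
#' @param ref_channel Reference (upstream) channel index; default 1.
#' @param dist_channel Distal (recovered) channel index; default 7.
#' @return Phase instant, s (attribute `index` carries the sample index).
#' @export
find_peak_drop_instant <- function(avg, ref_channel = 1, dist_channel = 7) {
  stopifnot(!is.null(avg$pressures), !is.null(avg$phase_time))
  if (max(ref_channel, dist_channel) > ncol(avg$pressures)) {
    stop("requested channels not present", call. = FALSE)
  }
  diff_trace <- avg$pressures[, ref_channel] - avg$pressures[, dist_channel]
  i <- which.max(diff_trace)  # which.max returns the first maximum
  structure(avg$phase_time[i], index = i)
}

#' Pressure-drop metrics from a beat-averaged tracing
#'
#' Implements the three transvalvular pressure-drop metrics:
#' \describe{
#'   \item{peak_drop}{instantaneous peak: at the instant `t*` of maximal
#'     reference-to-distal difference, the reference pressure minus the
#'     minimum of the modified-Akima spatial interpolant through all
#'     channels, searched on a dense grid;}
#'   \item{net_drop}{reference minus distal channel at `t*` (the
#'     irreversible drop remaining after pressure recovery);}
#'   \item{peak_to_peak_drop}{absolute difference between the temporal
#'     maxima of the reference and distal channels - maxima that in general
#'     occur at different instants, which is what exposes this metric to
#'     wave-reflection confounding.}
#' }
#'
#' @param avg A `beat_averaged_tracing`.
#' @param sensor_array A [sensor_array()]; defaults to the tracing's.
#' @param ref_channel Reference channel; default 1.
#' @param dist_channel Distal channel; default 7.
#' @param grid_mm Spatial search grid spacing, mm; default 1.
#' @param time_search `"peak-instant"` (default: locate `t*` from the
#'   reference/distal difference, then take the spatial minimum at `t*`) or
#'   `"all-instants"` (maximise the spatial-minimum drop over every phase
#'   instant; slower, kept as a sensitivity option).
#' @return An object of class `pressure_drop_metrics`: `peak_drop`,
#'   `net_drop`, `peak_to_peak_drop` (mmHg; `NA` for constant flow),
#'   `peak_instant` (s), `peak_location` (mm), `reference_channel`,
#'   `recovery_channel`.
#' @export
extract_metrics <- function(avg, sensor_array = avg$sensor_array,
                            ref_channel = 1, dist_channel = 7,
                            grid_mm = 1,
                            time_search = c("peak-instant", "all-instants")) {
  time_search <- match.arg(time_search)
  if (ncol(avg$pressures) < 2) {
    stop("at least 2 channels spanning the valve are required", call. = FALSE)
  }
  grid <- seq(min(sensor_array$positions), max(sensor_array$positions),
              by = grid_mm)

  spatial_min_at <- function(idx) {
    f <- makima_fun(sensor_array$positions, as.numeric(avg$pressures[idx, ]))
    vals <- f(grid)
    j <- which.min(vals)
    list(min = vals[j], location = grid[j])
  }

  if (time_search == "peak-instant") {
    t_star <- find_peak_drop_instant(avg, ref_channel, dist_channel)
    i_star <- attr(t_star, "index")
    sm <- spatial_min_at(i_star)
  } else {
    drops <- vapply(seq_len(nrow(avg$pressures)), function(i) {
      avg$pressures[i, ref_channel] - spatial_min_at(i)$min
    }, numeric(1))
    i_star <- which.max(drops)
    t_star <- structure(avg$phase_time[i_star], index = i_star)
    sm <- spatial_min_at(i_star)
  }

  ref_trace <- avg$pressures[, ref_channel]
  dist_trace <- avg$pressures[, dist_channel]
  structure(
    list(peak_drop = ref_trace[i_star] - sm$min,
         net_drop = ref_trace[i_star] - dist_trace[i_star],
         peak_to_peak_drop = abs(max(ref_trace) - max(dist_trace)),
         peak_instant = as.numeric(t_star),
         peak_location = sm$location,
         reference_channel = ref_channel,
         recovery_channel = dist_channel),
    class = "pressure_drop_metrics"
  )
}

#' Pressure-drop metrics from a constant-flow recording
#'
#' Constant flow has no cycle structure: each channel is averaged over the
#' full recording (the steady estimate), and the same spatial-interpolation
#' peak/net extraction is applied to the single time-averaged profile. The
#' peak-to-peak metric is not defined for constant flow and is reported as
#' `NA`.
#'
#' @inheritParams extract_metrics
#' @param recording A `sensor_recording` in constant mode.
#' @return A `pressure_drop_metrics` (with `peak_to_peak_drop = NA` and
#'   `peak_instant = NA`).
#' @export
extract_metrics_constant_flow <- function(recording,
                                          sensor_array = recording$sensor_array,
                                          ref_channel = 1, dist_channel = 7,
                                          grid_mm = 1) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (recording$condition$mode != "constant") {
    stop("constant-flow extraction requires a constant-mode recording; ",
         "use the pulsatile path", call. = FALSE)
  }
  means <- colMeans(recording$pressures)
  grid <- seq(min(sensor_array$positions), max(sensor_array$positions),
              by = grid_mm)
  f <- makima_fun(sensor_array$positions, as.numeric(means))
  vals <- f(grid)
  j <- which.min(vals)
  structure(
    list(peak_drop = unname(means[ref_channel] - vals[j]),
         net_drop = unname(means[ref_channel] - means[dist_channel]),
         peak_to_peak_drop = NA_real_,
         peak_instant = NA_real_,
         peak_location = grid[j],
         reference_channel = ref_channel,
         recovery_channel = dist_channel),
    class = "pressure_drop_metrics"
  )
}

#' @export
print.pressure_drop_metrics <- function(x, ...) {
  cat("<pressure_drop_metrics>\n")
  cat(sprintf("  peak drop:         %.3f mmHg at %+.0f mm%s\n",
              x$peak_drop, x$peak_location,
              if (is.na(x$peak_instant)) "" else
                sprintf(", t* = %.4f s", x$peak_instant)))
  cat(sprintf("  net drop:          %.3f mmHg (ch%d - ch%d)\n",
              x$net_drop, x$reference_channel, x$recovery_channel))
  if (is.na(x$peak_to_peak_drop)) {
    cat("  peak-to-peak drop: n/a (constant flow)\n")
  } else {
    cat(sprintf("  peak-to-peak drop: %.3f mmHg\n", x$peak_to_peak_drop))
  }
  invisible(x)
}

#' Full analysis pipeline for one recording
#'
#' Chains the pipeline the way the bench protocol does: zero-phase
#' Butterworth filtering, then (pulsatile) cycle segmentation and ensemble
#' averaging followed by metric extraction, or (constant flow) time
#' averaging and the same spatial extraction. Filtering precedes averaging
#' because pump artifacts are asynchronous with the cycle anchor and would
#' otherwise bias segmentation.
#'
#' @param recording A `sensor_recording`.
#' @param filter_order,filter_cutoff_hz Butterworth settings ([denoise()]).
#' @param ref_channel,dist_channel,grid_mm,time_search Passed to the
#'   extraction functions.
#' @param p2p_on_raw If `TRUE`, compute the peak-to-peak metric from the
#'   filtered raw traces instead of the ensemble-averaged tracing.
#' @return A `pressure_drop_metrics`, with attribute `details` (a list with
#'   `n_cycles`, `beat_variance`, `t_star`).
#' @examples
#' cfg <- phantom_config(sampling_rate = 2000, n_samples = 4000,
#'                       noise_broadband_sd = 0, turbulence_noise_amplitude = 0,
#'                       pump_artifact_amplitude = 0, reflection_coefficient = 0)
#' rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
#' analyze_recording(rec)
#' @export
analyze_recording <- function(recording, filter_order = 4,
                              filter_cutoff_hz = 50,
                              ref_channel = 1, dist_channel = 7,
                              grid_mm = 1,
                              time_search = "peak-instant",
                              p2p_on_raw = FALSE) {
  filtered <- denoise(recording, order = filter_order,
                      cutoff_hz = filter_cutoff_hz)
  if (recording$condition$mode == "constant") {
    m <- extract_metrics_constant_flow(filtered,
                                       ref_channel = ref_channel,
                                       dist_channel = dist_channel,
                                       grid_mm = grid_mm)
    attr(m, "details") <- list(n_cycles = NA_integer_,
                               beat_variance = NULL, t_star = NA_real_)
    return(m)
  }
  cycles <- segment_cycles(filtered, ref_channel = ref_channel)
  avg <- ensemble_average(filtered, cycles)
  m <- extract_metrics(avg, ref_channel = ref_channel,
                       dist_channel = dist_channel, grid_mm = grid_mm,
                       time_search = time_search)
  if (p2p_on_raw) {
    m$peak_to_peak_drop <- abs(max(filtered$pressures[, ref_channel]) -
                                 max(filtered$pressures[, dist_channel]))
  }
  attr(m, "details") <- list(n_cycles = avg$n_cycles_used,
                             beat_variance = avg$beat_variance,
                             t_star = m$peak_instant)
  m
}
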