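#' Segment a pulsatile recording into complete cardiac cycles
#'
#' Cycles are identified from the known pump period (`60 / heart_rate`),
#' anchored at the first detected upstroke of the reference channel (the
#' first upward crossing of 25 percent of its dynamic range). Only complete
#' cycles are returned; partial leading and trailing cycles are discarded.
#'
#' @param recording A `sensor_recording` (pulsatile).
#' @param heart_rate Heart rate, bpm; defaults to the recording's condition.
#' @param ref_channel Column used for upstroke detection; default 1.
#' @return Integer matrix with one row per complete cycle and columns
#'   `start`, `end` (inclusive sample indices).
#' @export
segment_cycles <- function(recording,
                           heart_rate = recording$condition$heart_rate,
                           ref_channel = 1) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (recording$condition$mode != "pulsatile") {
    stop("cycle segmentation requires a pulsatile recording", call. = FALSE)
  }
  if (is.null(heart_rate) || is.na(heart_rate) || heart_rate <= 0) {
    stop("a positive `heart_rate` is required", call. = FALSE)
  }
  period <- as.integer(round(recording$sampling_rate * 60 / heart_rate))
  p <- recording$pressures[, ref_channel]
  n <- length(p)
  if (n < 2 * period) {
    stop(sprintf(paste0("recording too short for cycle analysis: %d samples ",
                        "cover fewer than 2 cycles of %d samples"),
                 n, period), call. = FALSE)
  }
  thr <- min(p) + 0.25 * (max(p) - min(p))
  crossing <- which(p[-1] >= thr & p[-n] < thr)
  anchor <- if (length(crossing) == 0) 1L else crossing[1] + 1L
  n_cycles <- (n - anchor + 1L) %/% period
  if (n_cycles < 2) {
    stop(sprintf(paste0("only %d complete cycle(s) found after the first ",
                        "upstroke; at least 2 are required"),
                 n_cycles), call. = FALSE)
  }
  starts <- anchor + (seq_len(n_cycles) - 1L) * period
  cbind(start = starts, end = starts + period - 1L)
}

#' Ensemble (beat) average of a segmented recording
#'
#' Pointwise mean across cycles for each channel, yielding one mean
#' pressure tracing per channel over a single cycle, plus the per-channel
#' beat-to-beat variance (mean over phase of the across-cycle variance) as
#' the beat-to-beat reproducibility readout.
#'
#' @param recording A `sensor_recording`.
#' @param cycles Cycle index matrix from [segment_cycles()].
#' @return An object of class `beat_averaged_tracing`: `phase_time` (s),
#'   `pressures` (phase x channels, mmHg), `n_cycles_used`, `beat_variance`
#'   (per channel, mmHg^2), `sampling_rate`, `sensor_array`.
#' @export
ensemble_average <- function(recording, cycles) {
  stopifnot(inherits(recording, "sensor_recording"), is.matrix(cycles))
  if (nrow(cycles) < 2) {
    stop("at least 2 complete cycles are required for averaging", call. = FALSE)
  }
  lens <- cycles[, "end"] - cycles[, "start"] + 1L
  if (max(lens) - min(lens) > 1L) {
    stop("inconsistent cycle lengths (differ by more than 1 sample)",
         call. = FALSE)
  }
  len <- min(lens)
  n_ch <- ncol(recording$pressures)
  k <- nrow(cycles)
  avg <- matrix(0, len, n_ch, dimnames = list(NULL, colnames(recording$pressures)))
  beat_var <- numeric(n_ch)
  for (j in seq_len(n_ch)) {
    stack <- vapply(seq_len(k), function(i) {
      recording$pressures[cycles[i, "start"]:(cycles[i, "start"] + len - 1L), j]
    }, numeric(len))
    avg[, j] <- rowMeans(stack)
    beat_var[j] <- mean(rowSums((stack - avg[, j])^2) / (k - 1))
  }
  structure(
    list(phase_time = (seq_len(len) - 1) / recording$sampling_rate,
         pressures = avg,
         n_cycles_used = k,
         beat_variance = beat_var,
         sampling_rate = recording$sampling_rate,
         sensor_array = recording$sensor_array),
    class = "beat_averaged_tracing"
  )
}

#' @export
print.beat_averaged_tracing <- function(x, ...) {
  cat(sprintf("<beat_averaged_tracing> %d phase samples x %d channels, %d cycles\n",
              nrow(x$pressures), ncol(x$pressures), x$n_cycles_used))
  cat(sprintf("  beat-to-beat sd (mmHg): %s\n",
              paste(sprintf("%.3g", sqrt(x$beat_variance)), collapse = ", ")))
  invisible(x)
}
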