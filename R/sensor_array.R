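#' Pressure-port sensor array
#'
#' Describes the axial layout of wall pressure ports along the straight-tube
#' phantom. Positions are signed distances from the valve plane in mm
#' (negative = upstream). The default layout has 8 ports at
#' -30, +15, +30, +50, +75, +100, +200 and +500 mm: one port before the
#' valve, two in the jet region, four through the pressure-recovery zone and
#' one far downstream.
#'
#' @param positions Numeric vector of strictly increasing axial positions, mm.
#' @param channel_ids Integer channel labels, 1-based; default `1:length(positions)`.
#' @return An object of class `sensor_array`.
#' @examples
#' sensor_array()
#' @export
sensor_array <- function(positions = c(-30, 15, 30, 50, 75, 100, 200, 500),
                         channel_ids = seq_along(positions)) {
  if (!is.numeric(positions) || length(positions) < 2) {
    stop("`positions` must be a numeric vector of at least 2 ports", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(positions)) {
    stop("duplicate sensor positions", call. = FALSE)
  }
  if (length(channel_ids) != length(positions)) {
    stop("`channel_ids` must match `positions` in length", call. = FALSE)
  }
  structure(
    list(positions = as.numeric(positions),
         channel_ids = as.integer(channel_ids)),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", length(x$positions), " channels\n", sep = "")
  cat("  positions (mm): ", paste(x$positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_channels <- function(array) length(array$positions)

#' Flow condition
#'
#' Labels a pump regimen: pulsatile (cyclic output at a set heart rate,
#' clipped at zero by the non-return valve) or constant (steady output at
#' the peak flow rate). All acquisitions in the reference protocol use
#' 75 bpm and peak flows of 100, 150, 200 or 250 ml/s.
#'
#' @param mode `"pulsatile"` or `"constant"`.
#' @param peak_flow Peak volumetric flow rate, ml/s; non-negative.
#' @param heart_rate Heart rate in beats/min; required for pulsatile mode.
#' @return An object of class `flow_condition`.
#' @examples
#' flow_condition("pulsatile", peak_flow = 250)
#' flow_condition("constant", peak_flow = 100)
#' @export
flow_condition <- function(mode = c("pulsatile", "constant"),
                           peak_flow = 250,
                           heart_rate = if (mode == "pulsatile") 75 else NA_real_) {
  mode <- match.arg(mode)
  if (!is.numeric(peak_flow) || length(peak_flow) != 1 || !is.finite(peak_flow) ||
      peak_flow < 0) {
    stop("`peak_flow` must be a single non-negative number (ml/s)", call. = FALSE)
  }
  if (mode == "pulsatile") {
    if (is.null(heart_rate) || is.na(heart_rate) || !is.numeric(heart_rate) ||
        heart_rate <= 0) {
      stop("pulsatile mode requires a positive `heart_rate` (bpm)", call. = FALSE)
    }
  } else {
    heart_rate <- NA_real_
  }
  structure(
    list(mode = mode, peak_flow = as.numeric(peak_flow),
         heart_rate = as.numeric(heart_rate)),
    class = "flow_condition"
  )
}

#' @export
print.flow_condition <- function(x, ...) {
  if (x$mode == "pulsatile") {
    cat(sprintf("<flow_condition> pulsatile, peak %g ml/s @ %g bpm\n",
                x$peak_flow, x$heart_rate))
  } else {
    cat(sprintf("<flow_condition> constant, %g ml/s\n", x$peak_flow))
  }
  invisible(x)
}
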