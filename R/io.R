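#' Write / read a recording as CSV plus a metadata sidecar
#'
#' The on-disk format is a plain CSV with columns `time_s, ch1..chN`
#' (mmHg), written with 17 significant digits so that doubles round-trip
#' bit-exactly, plus a YAML sidecar (`<path>.yaml`) holding the sensor
#' positions, acquisition metadata, flow condition, seed, provenance and
#' (if present) the generator ground-truth scalars. The reader validates
#' the sidecar against the data: channel count must match the positions,
#' and the time column must be strictly increasing. The ground-truth flow
#' waveform is not serialised.
#'
#' @param recording A `sensor_recording`.
#' @param path Path of the CSV file; the sidecar is written next to it.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `sensor_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  n_ch <- ncol(recording$pressures)
  header <- paste(c("time_s", paste0("ch", seq_len(n_ch))), collapse = ",")
  body <- do.call(paste, c(
    lapply(seq_len(n_ch + 1), function(j) {
      v <- if (j == 1) recording$time else recording$pressures[, j - 1]
      sprintf("%.17g", v)
    }), sep = ","))
  writeLines(c(header, body), path)

  gt <- recording$ground_truth
  meta <- list(
    positions_mm = as.numeric(recording$sensor_array$positions),
    channel_ids = as.integer(recording$sensor_array$channel_ids),
    sampling_rate_hz = recording$sampling_rate,
    mode = recording$condition$mode,
    peak_flow_ml_s = recording$condition$peak_flow,
    heart_rate_bpm = recording$condition$heart_rate,
    seed = recording$seed,
    provenance = recording$provenance,
    ground_truth = if (!is.null(gt)) list(
      true_peak_drop = gt$true_peak_drop,
      true_net_drop = gt$true_net_drop,
      true_peak_instant = gt$true_peak_instant,
      true_peak_location = gt$true_peak_location))
  yaml::write_yaml(meta, sidecar_path(path), precision = 17)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing metadata sidecar: ", side, call. = FALSE)
  }
  meta <- yaml::read_yaml(side)
  req <- c("positions_mm", "sampling_rate_hz", "mode", "peak_flow_ml_s")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop("malformed sidecar ", side, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (names(dat)[1] != "time_s") {
    stop(path, ", line 1: first column must be time_s", call. = FALSE)
  }
  n_ch <- ncol(dat) - 1
  if (n_ch != length(meta$positions_mm)) {
    stop(sprintf("%s: %d pressure channels but %d positions in sidecar",
                 path, n_ch, length(meta$positions_mm)), call. = FALSE)
  }
  time <- dat[[1]]
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop(sprintf("%s, line %d: time column is not strictly increasing",
                 path, bad[1] + 2L), call. = FALSE)
  }
  array <- sensor_array(meta$positions_mm,
                        channel_ids = meta$channel_ids %||% seq_len(n_ch))
  condition <- flow_condition(meta$mode, peak_flow = meta$peak_flow_ml_s,
                              heart_rate = meta$heart_rate_bpm %||% NA_real_)
  gt <- if (!is.null(meta$ground_truth)) {
    structure(c(meta$ground_truth, list(flow_waveform = NULL)),
              class = "ground_truth")
  }
  pressures <- as.matrix(dat[, -1, drop = FALSE])
  colnames(pressures) <- paste0("ch", array$channel_ids)
  structure(
    list(time = time, pressures = pressures, sensor_array = array,
         condition = condition, ground_truth = gt,
         provenance = meta$provenance %||% list(),
         sampling_rate = meta$sampling_rate_hz,
         seed = meta$seed %||% NA_integer_),
    class = "sensor_recording"
  )
}

sidecar_path <- function(path) paste0(path, ".yaml")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a phantom configuration as YAML
#'
#' Human-readable round-trip of a [phantom_config()]; field names in the
#' file mirror the constructor arguments, with the sensor array nested
#' under `sensor_array`.
#'
#' @param config A `phantom_config`.
#' @param path File path.
#' @export
write_phantom_config <- function(config, path) {
  validate_phantom_config(config)
  lst <- unclass(config)
  lst$sensor_array <- list(positions = as.numeric(config$sensor_array$positions),
                           channel_ids = as.integer(config$sensor_array$channel_ids))
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$sensor_array <- sensor_array(lst$sensor_array$positions,
                                   lst$sensor_array$channel_ids)
  do.call(phantom_config, lst)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the command label, arguments,
#' seed, input and output paths with MD5 hashes, package version and a
#' timestamp - enough to re-run the step bit-identically.
#'
#' @param path Manifest path (JSON).
#' @param command Free-text command label.
#' @param args Named list of arguments (must be JSON-serialisable).
#' @param seed Integer seed used by the step.
#' @param inputs,outputs Character vectors of file paths; existing files
#'   are hashed.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, args = list(), seed = NA_integer_,
                           inputs = character(), outputs = character()) {
  hash_files <- function(paths) {
    if (length(paths) == 0) return(NULL)
    h <- tools::md5sum(paths[file.exists(paths)])
    as.list(h)
  }
  manifest <- list(
    command = command,
    args = args,
    seed = seed,
    inputs = hash_files(inputs),
    outputs = hash_files(outputs),
    package_version = as.character(packageVersion("flowphantom")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
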