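#' Write a recording to disk as CSV plus JSON sidecar
#'
#' The on-disk dialect is a headered CSV (`time` in seconds, then one column
#' per channel; UTF-8, `.` decimal, LF line endings) with a JSON sidecar
#' holding the sampling rate, condition, block id and stimulation frequency.
#' [read_recording()] inverts it exactly (the CSV writer uses shortest
#' round-trip decimal representations).
#'
#' @param rec a valid [tremor_recording()].
#' @param path file path without extension; `<path>.csv` and `<path>.json`
#'   are written.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "tremor_recording")) {
    stop_tremor("`rec` must be a tremor_recording.", "validation")
  }
  vals <- as.matrix(rec$data[rec$channel_names])
  if (any(!is.finite(vals))) {
    stop_tremor("Refusing to write a recording containing non-finite samples.",
                "validation")
  }
  if (length(rec$channel_names) == 0L) {
    stop_tremor("Refusing to write a recording with no channels.", "validation")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_tremor(sprintf("Directory does not exist: %s", dir), "io")
  }
  # shortest-round-trip decimal text so read_recording inverts bit-exactly
  chr <- rec$data
  for (nm in names(chr)) chr[[nm]] <- sprintf("%.17g", chr[[nm]])
  readr::write_csv(chr, paste0(path, ".csv"))
  meta <- list(
    fs = rec$fs, block_id = rec$block_id, condition = rec$condition,
    stim_freq = if (is.na(rec$stim_freq)) NULL else rec$stim_freq,
    duration_s = rec$duration_s, channel_names = as.list(rec$channel_names)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path without extension (the `.csv`/`.json` pair).
#' @return a [tremor_recording()].
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv")
  sidecar <- paste0(path, ".json")
  if (!file.exists(csv)) {
    stop_tremor(sprintf("Samples file not found: %s", csv), "format")
  }
  if (!file.exists(sidecar)) {
    stop_tremor(sprintf("Missing JSON sidecar: %s", sidecar), "format")
  }
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
    stop_tremor("Sidecar `fs` must be a positive number.", "validation")
  }
  # parse via strtod (correctly rounded) so the text dialect round-trips
  # bit-exactly; readr's fast double path can be off by an ulp
  data <- readr::read_csv(csv, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  for (nm in names(data)) {
    num <- suppressWarnings(as.numeric(data[[nm]]))
    bad <- which(is.na(num) & !is.na(data[[nm]]))
    if (length(bad)) {
      stop_tremor(sprintf("Non-numeric cell in %s (column %s, row %d: '%s').",
                          csv, nm, bad[1], data[[nm]][bad[1]]), "parse")
    }
    data[[nm]] <- num
  }
  tremor_recording(
    data, fs = meta$fs, block_id = meta$block_id %||% "b01",
    condition = meta$condition %||% "initial",
    stim_freq = meta$stim_freq %||% NA_real_,
    duration_s = meta$duration_s %||% NULL
  )
}

config_defaults <- function() {
  list(
    passband_half_width_hz = 1.0,  # Butterworth cutoffs at peak +/- this
    filter_order = 3L,
    n_tapers = 12L,
    time_bandwidth = NULL,         # NULL -> (n_tapers + 1) / 2
    hist_bins = 20L,
    profile_min_hz = 0.0,
    profile_max_hz = 20.0,
    profile_step_hz = 0.1,
    smoothing_width_hz = 1.0,
    smoothing_kernel = "gaussian", # gaussian | boxcar; a peaked kernel keeps
                                   # the profile argmax at a locked frequency
    edge_trim_s = 2.0,             # discarded at both ends after filtering
    exclude_ramp = FALSE,          # drop the first 2 x ramp_s of each block
    ramp_s = 10.0,
    peak_band_hz = c(4, 14),
    decimate_to_hz = NULL,         # NULL = no decimation
    boxcox_lambda_min = -2.0,
    boxcox_lambda_max = 2.0,
    boxcox_lambda_step = 0.01,
    boxcox_target = "envelope",    # envelope | signal (ambiguous ordering flag)
    solver_tol = 1e-9,
    solver_max_iter = 20000L,
    seed = NULL
  )
}

#' Build a pipeline configuration
#'
#' Returns the full set of analysis tunables with their defaults, overridden
#' by any named arguments. Unknown names are rejected, as are out-of-range
#' values (for example a non-positive profile step).
#'
#' @param ... named overrides of the documented defaults.
#' @return a named list of class `tremor_config`.
#' @examples
#' cfg <- tremor_config(hist_bins = 20)
#' cfg$profile_step_hz
#' @export
tremor_config <- function(...) {
  defaults <- config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop_tremor("All configuration overrides must be named.", "config")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop_tremor(sprintf("Unknown configuration key(s): %s.",
                        paste(unknown, collapse = ", ")), "config")
  }
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  check_number(cfg$passband_half_width_hz, "passband_half_width_hz",
               lower = .Machine$double.eps)
  check_number(cfg$filter_order, "filter_order", lower = 1)
  check_number(cfg$n_tapers, "n_tapers", lower = 1)
  check_number(cfg$time_bandwidth, "time_bandwidth", lower = 0.5, allow_null = TRUE)
  check_number(cfg$hist_bins, "hist_bins", lower = 2)
  check_number(cfg$profile_min_hz, "profile_min_hz", lower = 0)
  check_number(cfg$profile_max_hz, "profile_max_hz",
               lower = cfg$profile_min_hz + .Machine$double.eps)
  check_number(cfg$profile_step_hz, "profile_step_hz", lower = .Machine$double.eps)
  check_number(cfg$smoothing_width_hz, "smoothing_width_hz", lower = 0)
  if (!cfg$smoothing_kernel %in% c("boxcar", "gaussian")) {
    stop_tremor("smoothing_kernel must be 'boxcar' or 'gaussian'.", "validation")
  }
  check_number(cfg$edge_trim_s, "edge_trim_s", lower = 0)
  check_number(cfg$ramp_s, "ramp_s", lower = 0)
  if (!is.numeric(cfg$peak_band_hz) || length(cfg$peak_band_hz) != 2L ||
      cfg$peak_band_hz[1] >= cfg$peak_band_hz[2]) {
    stop_tremor("peak_band_hz must be an increasing pair of frequencies.", "validation")
  }
  check_number(cfg$decimate_to_hz, "decimate_to_hz", lower = 1, allow_null = TRUE)
  check_number(cfg$boxcox_lambda_step, "boxcox_lambda_step", lower = 1e-6)
  if (!cfg$boxcox_target %in% c("envelope", "signal")) {
    stop_tremor("boxcox_target must be 'envelope' or 'signal'.", "validation")
  }
  check_number(cfg$solver_tol, "solver_tol", lower = .Machine$double.xmin)
  check_number(cfg$solver_max_iter, "solver_max_iter", lower = 1)
  check_number(cfg$seed, "seed", allow_null = TRUE)
  structure(cfg, class = c("tremor_config", "list"))
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' An empty or missing-key file yields the documented defaults; unknown keys
#' and out-of-range values are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return a `tremor_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(tremor_config())
  if (!file.exists(path)) {
    stop_tremor(sprintf("Config file not found: %s", path), "config")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_tremor("Config file must contain a mapping.", "config")
  do.call(tremor_config, raw)
}
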