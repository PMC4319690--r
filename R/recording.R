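#' Condition labels used by the block design
#'
#' The closed set of experimental conditions: four tACS return-electrode
#' montages (fronto-orbital `FO`, contralateral M1 `cM1`, left and right
#' shoulder `LSh`/`RSh`), `sham`, `photic` flicker, and the long `initial`
#' tremor recording used to determine the stimulation frequency.
#'
#' @export
tremor_conditions <- c("FO", "cM1", "LSh", "RSh", "sham", "photic", "initial")

#' Construct a multi-channel tremor recording
#'
#' A `tremor_recording` bundles a samples table (a tibble with a `time` column
#' plus one column per channel, typically `acc_x`, `acc_y`, `acc_z` and a
#' `stim` or `photic` reference channel) with its acquisition metadata. It is
#' the unit every analysis stage consumes.
#'
#' @param data tibble or data frame with a `time` column (seconds) and at
#'   least one channel column; all values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param block_id short string identifying the block.
#' @param condition one of [tremor_conditions].
#' @param stim_freq stimulation frequency in Hz, or `NA` when no stimulation
#'   was scheduled for the block.
#' @param duration_s block duration in seconds; defaults to `nrow(data) / fs`.
#'   Must satisfy `nrow(data) == round(duration_s * fs)`.
#' @return an object of class `tremor_recording`.
#' @examples
#' t <- seq(0, 2, by = 1 / 64)[-129]
#' rec <- tremor_recording(
#'   tibble::tibble(time = t, acc_x = sin(2 * pi * 8 * t)),
#'   fs = 64, block_id = "b01", condition = "sham"
#' )
#' rec
#' @export
tremor_recording <- function(data, fs, block_id = "b01", condition = "initial",
                             stim_freq = NA_real_, duration_s = NULL) {
  data <- as_tibble(data)
  if (!"time" %in% names(data)) {
    stop_tremor("Recording data must contain a `time` column.", "validation")
  }
  channels <- setdiff(names(data), "time")
  if (length(channels) == 0L) {
    stop_tremor("Recording must have at least one channel.", "validation")
  }
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% tremor_conditions) {
    stop_tremor(
      sprintf("`condition` must be one of: %s.", paste(tremor_conditions, collapse = ", ")),
      "validation"
    )
  }
  vals <- as.matrix(data[channels])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_tremor("All recording samples must be finite numbers.", "validation")
  }
  duration_s <- duration_s %||% (nrow(data) / fs)
  if (nrow(data) != round(duration_s * fs)) {
    stop_tremor(
      sprintf("Sample count %d inconsistent with duration %g s at %g Hz.",
              nrow(data), duration_s, fs),
      "validation"
    )
  }
  if (!is.na(stim_freq)) check_number(stim_freq, "stim_freq", lower = 0)
  structure(
    list(data = data, fs = fs, channel_names = channels, block_id = block_id,
         condition = condition, stim_freq = as.double(stim_freq),
         duration_s = duration_s),
    class = "tremor_recording"
  )
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf(
    "<tremor_recording> block %s | condition %s | %g s @ %g Hz | channels: %s\n",
    x$block_id, x$condition, x$duration_s, x$fs,
    paste(x$channel_names, collapse = ", ")
  ))
  if (!is.na(x$stim_freq)) cat(sprintf("  stimulation frequency: %g Hz\n", x$stim_freq))
  invisible(x)
}

#' @export
as_tibble.tremor_recording <- function(x, ...) x$data

#' Extract channels from a recording as a numeric matrix
#'
#' @param rec a [tremor_recording()].
#' @param channels channel names; defaults to the accelerometer channels
#'   (those starting with `"acc"`).
#' @return numeric matrix, one column per channel.
#' @export
recording_channels <- function(rec, channels = NULL) {
  stopifnot(inherits(rec, "tremor_recording"))
  channels <- channels %||% grep("^acc", rec$channel_names, value = TRUE)
  missing <- setdiff(channels, rec$channel_names)
  if (length(missing)) {
    stop_tremor(sprintf("Unknown channel(s): %s.", paste(missing, collapse = ", ")),
                "validation")
  }
  as.matrix(rec$data[channels])
}

#' Assemble a block-design manifest
#'
#' Describes one subject's session: an ordered set of experimental blocks with
#' their conditions and stimulation frequency. The full protocol comprises two
#' cycles of six randomly interleaved blocks (four tACS montages, photic, and
#' sham), preceded by a long stimulation-free `initial` recording.
#'
#' @param subject_id subject label.
#' @param stim_freq stimulation frequency (Hz) shared by all stimulated blocks.
#' @param seed optional integer controlling the random interleaving.
#' @param rest_s rest between blocks (metadata only), seconds.
#' @return tibble with columns `subject_id`, `block_id`, `condition`,
#'   `stim_freq`; attribute `rest_s`.
#' @examples
#' block_design("s01", stim_freq = 8.3, seed = 1)
#' @export
block_design <- function(subject_id, stim_freq, seed = NULL, rest_s = 120) {
  check_number(stim_freq, "stim_freq", lower = .Machine$double.eps)
  conds <- setdiff(tremor_conditions, "initial")
  order_fun <- function() sample(conds)
  cycle <- if (is.null(seed)) {
    c(order_fun(), order_fun())
  } else {
    withr::with_seed(seed, c(order_fun(), order_fun()))
  }
  out <- tibble(
    subject_id = subject_id,
    block_id = sprintf("b%02d", seq_along(cycle)),
    condition = cycle,
    stim_freq = stim_freq
  )
  validate_block_design(out)
  attr(out, "rest_s") <- rest_s
  out
}

validate_block_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("block_id", "condition", "stim_freq")
  if (!all(need %in% names(design))) {
    stop_tremor("Design must have columns block_id, condition, stim_freq.", "validation")
  }
  if (anyDuplicated(design$block_id)) {
    stop_tremor("Duplicate block_ids in design.", "validation")
  }
  if (!all(design$condition %in% setdiff(tremor_conditions, "initial"))) {
    stop_tremor("Design conditions must come from the experimental condition set.",
                "validation")
  }
  stim <- unique(design$stim_freq[!is.na(design$stim_freq)])
  if (length(stim) > 1L) {
    stop_tremor("stim_freq must be identical across a subject's blocks.", "validation")
  }
  invisible(design)
}
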