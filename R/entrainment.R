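#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic extension of a real band-limited series by
#' the FFT half-spectrum method; its argument is the instantaneous phase and
#' its modulus the amplitude envelope. Edge transients should be trimmed
#' upstream (the pipeline discards the configured `edge_trim_s` at both ends
#' after filtering).
#'
#' @param x univariate numeric series (band-passed; length > `4 * fs`).
#' @param fs sampling rate, Hz.
#' @return list of class `analytic_signal` with `phase` (radians, in
#'   `(-pi, pi]`), `envelope` (>= 0) and `fs`.
#' @examples
#' t <- seq(0, 10, by = 1 / 64)[-1]
#' a <- analytic_signal(cos(2 * pi * 8 * t), fs = 64)
#' range(a$envelope[100:500])
#' @export
analytic_signal <- function(x, fs) {
  n <- length(x)
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (n <= 4 * fs) {
    stop_tremor("Series must be longer than 4 s for phase extraction.", "length")
  }
  if (sd(x) < .Machine$double.eps) {
    stop_tremor("Constant series has no instantaneous phase.", "degenerate")
  }
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  structure(list(phase = Arg(z), envelope = Mod(z), fs = fs),
            class = "analytic_signal")
}

#' Mean instantaneous frequency of an analytic signal
#'
#' @param a an [analytic_signal()].
#' @return Hz, from the mean unwrapped phase increment.
#' @export
instantaneous_frequency <- function(a) {
  stopifnot(inherits(a, "analytic_signal"))
  d <- wrap_phase(diff(a$phase))
  d * a$fs / (2 * pi)
}

#' Box-Cox variance stabilization
#'
#' Transforms a positive series with `(x^lambda - 1) / lambda` (natural log at
#' `lambda = 0`), choosing `lambda` by profile maximum likelihood on a grid
#' (default \[-2, 2\] in steps of 0.01). Applied per block to the Hilbert
#' amplitude envelope, whose multiplicative fluctuations otherwise couple the
#' local mean and variance.
#'
#' @param x positive numeric series.
#' @param shift offset added before transforming (default 0).
#' @param lambda_grid candidate exponents.
#' @return list of class `boxcox_result` with `transformed`, `lambda`,
#'   `shift`.
#' @export
boxcox_stabilize <- function(x, shift = 0,
                             lambda_grid = seq(-2, 2, by = 0.01)) {
  y <- x + shift
  if (length(y) == 0L) stop_tremor("Empty input.", "validation")
  if (any(!is.finite(y))) stop_tremor("Input must be finite.", "validation")
  if (any(y <= 0)) {
    stop_tremor("Box-Cox requires strictly positive values (consider `shift`).",
                "domain")
  }
  n <- length(y)
  logy <- log(y)
  slogy <- sum(logy)
  ll <- vapply(lambda_grid, function(l) {
    z <- if (abs(l) < 1e-8) logy else (y^l - 1) / l
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (l - 1) * slogy
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  transformed <- if (abs(lambda) < 1e-8) logy else (y^lambda - 1) / lambda
  structure(list(transformed = transformed, lambda = lambda, shift = shift),
            class = "boxcox_result")
}

#' Wrapped phase difference between two phase series
#'
#' @param phase_a,phase_b equal-length numeric vectors of phases (radians).
#' @return numeric vector `wrap(a - b)` in `(-pi, pi]`.
#' @export
phase_difference <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop_tremor("Phase series must have equal length.", "validation")
  }
  wrap_phase(phase_a - phase_b)
}

#' Phase synchronization index
#'
#' Magnitude of the mean unit phasor of a phase-difference series,
#' `|mean(exp(i * phi_t))|` — the phase-locking-value normalisation, under
#' which PSI is 0 for a uniformly distributed phase difference and 1 for a
#' constant one.
#'
#' @param phi numeric vector of phase differences (radians).
#' @return value in \[0, 1\].
#' @examples
#' psi(rep(0.7, 1000))        # perfectly synchronized
#' psi(seq(0, 2 * pi, length.out = 361)[-361])  # uniform: ~0
#' @export
psi <- function(phi) {
  if (length(phi) == 0L) stop_tremor("Empty phase-difference series.", "validation")
  if (any(!is.finite(phi))) stop_tremor("Phases must be finite.", "validation")
  Mod(mean(exp(1i * phi)))
}

#' Phase-difference likelihood histogram
#'
#' Stratifies the phase difference into uniform bins over `(-pi, pi]` and
#' normalises counts to a probability distribution.
#'
#' @param phi numeric vector of phase differences (radians; wrapped
#'   internally).
#' @param n_bins number of bins (default 20).
#' @return tibble of class `phase_histogram` with `lower`, `upper`, `center`,
#'   `prob`.
#' @export
phase_histogram <- function(phi, n_bins = 20) {
  if (!is.numeric(n_bins) || n_bins < 2) {
    stop_tremor("n_bins must be >= 2.", "validation")
  }
  n_bins <- as.integer(n_bins)
  phi <- wrap_phase(phi)
  idx <- ceiling((phi + pi) / (2 * pi) * n_bins)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  out <- tibble(
    lower = edges[-(n_bins + 1L)], upper = edges[-1L],
    center = (edges[-(n_bins + 1L)] + edges[-1L]) / 2,
    prob = counts / sum(counts)
  )
  structure(out, class = c("phase_histogram", class(out)))
}

#' Amplitude-modulation PSI
#'
#' Quantifies how strongly the amplitude envelope is modulated by the
#' phase-difference: the envelope is averaged within each phase-difference
#' bin, the bin means are normalised to a probability distribution `p_b`, and
#' the index is `|sum_b p_b exp(i theta_b)|` over bin centres `theta_b`. A
#' phase-independent envelope gives ~0; an envelope concentrated at one
#' phase gives values toward 1.
#'
#' @param envelope nonnegative amplitude series.
#' @param phi phase-difference series, same length.
#' @param n_bins number of phase bins (default 20).
#' @return value in \[0, 1\].
#' @export
amplitude_modulation_psi <- function(envelope, phi, n_bins = 20) {
  if (length(envelope) != length(phi)) {
    stop_tremor("envelope and phi must have equal length.", "validation")
  }
  if (any(!is.finite(envelope)) || any(envelope < 0)) {
    stop_tremor("envelope must be finite and >= 0.", "validation")
  }
  if (sum(envelope) <= 0) {
    stop_tremor("All-zero envelope carries no modulation information.", "degenerate")
  }
  n_bins <- as.integer(n_bins)
  phi <- wrap_phase(phi)
  idx <- ceiling((phi + pi) / (2 * pi) * n_bins)
  idx[idx < 1L] <- 1L
  sums <- vapply(seq_len(n_bins), function(b) sum(envelope[idx == b]), numeric(1))
  cnts <- tabulate(idx, nbins = n_bins)
  means <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  p <- means / sum(means)
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  Mod(sum(p * exp(1i * centers)))
}

#' Phase-stability profile over a reference-frequency grid
#'
#' Substitutes artificial sinusoidal references (phase `2 pi f t`, zero
#' initial phase — PSI is invariant to the reference's initial phase) for the
#' stimulation waveform at each frequency of a 0-20 Hz grid (step 0.1 Hz by
#' default), computes the PSI between the tremor phase and each reference,
#' and smooths the profile with a centred kernel of total width
#' `smoothing_width` Hz (edges reflected). The default kernel is gaussian:
#' under strong entrainment the raw profile approaches a single-bin spike at
#' the locked frequency, and a flat boxcar would turn it into an 11-bin
#' plateau whose argmax is decided by noise; a peaked kernel keeps the
#' maximum at the locked frequency. A boxcar is available via `kernel`.
#' The maximum of the smoothed profile is the per-block entrainment
#' statistic.
#'
#' @param x a band-passed numeric series, or an [analytic_signal()].
#' @param fs sampling rate, Hz (ignored when `x` is an analytic signal).
#' @param fmin,fmax,step frequency grid (Hz); defaults 0, 20, 0.1.
#' @param smoothing_width kernel width in Hz (default 1).
#' @param kernel `"gaussian"` (default) or `"boxcar"`.
#' @return tibble of class `stability_profile` with `freq`, `psi` (smoothed)
#'   and `psi_raw`.
#' @export
stability_profile <- function(x, fs = NULL, fmin = 0, fmax = 20, step = 0.1,
                              smoothing_width = 1, kernel = c("gaussian", "boxcar")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop_tremor("Grid step must be > 0.", "validation")
  }
  a <- if (inherits(x, "analytic_signal")) x else analytic_signal(x, fs)
  freqs <- seq(fmin, fmax, by = step)
  n <- length(a$phase)
  t <- (seq_len(n) - 1) / a$fs
  z <- exp(1i * a$phase)
  raw <- vapply(freqs, function(f) Mod(mean(z * exp(-1i * 2 * pi * f * t))),
                numeric(1))
  sm <- smooth_profile(raw, step, smoothing_width, kernel)
  out <- tibble(freq = freqs, psi = sm, psi_raw = raw)
  structure(out, class = c("stability_profile", class(out)),
            smoothing_width = smoothing_width, kernel = kernel, fs = a$fs)
}

# Centred moving average (or gaussian) with reflected edges; width in Hz.
smooth_profile <- function(p, step, width, kernel = "boxcar") {
  half <- floor(width / step / 2)
  if (width <= 0 || half < 1) return(p)
  if (kernel == "boxcar") {
    w <- rep(1, 2L * half + 1L)
  } else {
    xs <- seq(-half, half) * step
    w <- exp(-0.5 * (xs / (width / 4))^2)
  }
  w <- w / sum(w)
  n <- length(p)
  padded <- c(p[(half + 1):2], p, p[(n - 1):(n - half)])
  as.numeric(stats::filter(padded, w, sides = 2))[(half + 1):(half + n)]
}

#' Per-block entrainment metrics
#'
#' The per-block statistic is the maximum of the smoothed phase-stability
#' profile (its frequency recorded alongside; ties break toward the lower
#' frequency), together with the amplitude-modulation PSI and the Box-Cox
#' exponent used for that block.
#'
#' @param profile a [stability_profile()].
#' @param amp_mod amplitude-modulation PSI for the block (optional).
#' @param lambda Box-Cox exponent for the block (optional).
#' @return one-row tibble with `max_psi`, `argmax_freq`, `amp_mod_psi`,
#'   `boxcox_lambda`.
#' @export
block_metrics <- function(profile, amp_mod = NA_real_, lambda = NA_real_) {
  stopifnot(is.data.frame(profile), all(c("freq", "psi") %in% names(profile)))
  if (any(!is.finite(profile$psi)) ||
      any(profile$psi < -1e-12) || any(profile$psi > 1 + 1e-12)) {
    stop_tremor("Profile PSI values must lie in [0, 1].", "validation")
  }
  i <- which.max(profile$psi)  # first index = lowest frequency on ties
  tibble(
    max_psi = profile$psi[i], argmax_freq = profile$freq[i],
    amp_mod_psi = amp_mod, boxcox_lambda = lambda
  )
}

#' Sham-baselined condition summaries
#'
#' Averages the per-block maximum PSI within each condition and expresses
#' each stimulated condition relative to the mean over the sham blocks:
#' `pct_change = 100 * (mean_max_psi - sham_baseline) / sham_baseline`.
#'
#' @param metrics tibble of per-block metrics with at least `condition` and
#'   `max_psi` columns (`amp_mod_psi` and `subject_id` are carried through
#'   when present). `initial` blocks are excluded.
#' @param sham_condition label of the baseline condition (default "sham").
#' @return tibble with one row per condition (sham included with
#'   `pct_change = 0`): `condition`, `n_blocks`, `mean_max_psi`,
#'   `sham_baseline`, `pct_change`, `mean_amp_mod_psi`.
#' @export
condition_summary <- function(metrics, sham_condition = "sham") {
  stopifnot(is.data.frame(metrics),
            all(c("condition", "max_psi") %in% names(metrics)))
  metrics <- filter(metrics, .data$condition != "initial")
  sham <- metrics$max_psi[metrics$condition == sham_condition]
  if (length(sham) == 0L) {
    stop_tremor("At least one sham block is required for the baseline.", "validation")
  }
  baseline <- mean(sham)
  if (baseline <= 0) {
    stop_tremor("Sham baseline PSI must be > 0.", "degenerate")
  }
  if (!"amp_mod_psi" %in% names(metrics)) metrics$amp_mod_psi <- NA_real_
  out <- metrics |>
    group_by(.data$condition) |>
    summarise(
      n_blocks = n(),
      mean_max_psi = mean(.data$max_psi),
      mean_amp_mod_psi = mean(.data$amp_mod_psi),
      .groups = "drop"
    ) |>
    mutate(
      sham_baseline = baseline,
      pct_change = 100 * (.data$mean_max_psi - baseline) / baseline
    ) |>
    select("condition", "n_blocks", "mean_max_psi", "sham_baseline",
           "pct_change", "mean_amp_mod_psi")
  if ("subject_id" %in% names(metrics)) {
    out <- mutate(out, subject_id = metrics$subject_id[1], .before = 1)
  }
  out
}

#' Analyse one recording block
#'
#' Runs the full per-block pipeline: optional decimation, first principal
#' component of the accelerometer channels, multitaper spectral peak within
#' the physiological band, zero-phase band-pass centred on that block's peak,
#' edge trimming, Hilbert phase/envelope, Box-Cox stabilization of the
#' envelope, the phase-stability profile, and the amplitude-modulation PSI
#' against the reference at the block's stimulation frequency (the recorded
#' stimulation sinusoid's phase equals the artificial reference phase up to a
#' constant, to which PSI is invariant; for sham blocks the scheduled
#' frequency is used).
#'
#' @param rec a [tremor_recording()].
#' @param config a [tremor_config()].
#' @param keep_profile attach the profile tibble as a list-column.
#' @return one-row tibble: `block_id`, `condition`, `stim_freq`, `peak_freq`,
#'   `max_psi`, `argmax_freq`, `amp_mod_psi`, `boxcox_lambda` (+ `profile`
#'   list-column when requested).
#' @export
analyze_block <- function(rec, config = tremor_config(), keep_profile = FALSE) {
  stopifnot(inherits(rec, "tremor_recording"))
  pc <- first_principal_component(rec)
  series <- pc$series
  fs <- rec$fs
  if (!is.null(config$decimate_to_hz) && config$decimate_to_hz < fs) {
    dec <- decimate_series(series, fs, config$decimate_to_hz)
    series <- dec$series
    fs <- dec$fs
  }
  est <- multitaper_psd(series, fs, n_tapers = config$n_tapers,
                        nw = config$time_bandwidth)
  peak <- detect_peak_frequency(est, band = config$peak_band_hz)
  filt <- zero_phase_bandpass(series, fs, center = peak,
                              half_width = config$passband_half_width_hz,
                              order = config$filter_order)
  drop_head <- round(config$edge_trim_s * fs)
  if (isTRUE(config$exclude_ramp) && rec$condition != "initial") {
    drop_head <- max(drop_head, round(2 * config$ramp_s * fs))
  }
  drop_tail <- round(config$edge_trim_s * fs)
  keep <- seq.int(drop_head + 1L, length(filt) - drop_tail)
  a <- analytic_signal(filt[keep], fs)

  env <- a$envelope
  shift <- if (any(env <= 0)) min(env[env > 0]) / 2 - min(env) else 0
  bc <- boxcox_stabilize(env, shift = shift,
                         lambda_grid = seq(config$boxcox_lambda_min,
                                           config$boxcox_lambda_max,
                                           by = config$boxcox_lambda_step))

  prof <- stability_profile(
    a, fmin = config$profile_min_hz, fmax = config$profile_max_hz,
    step = config$profile_step_hz,
    smoothing_width = config$smoothing_width_hz,
    kernel = config$smoothing_kernel
  )

  ref_freq <- if (!is.na(rec$stim_freq)) rec$stim_freq else peak
  t <- (seq_along(a$phase) - 1) / fs
  phi <- phase_difference(a$phase, wrap_phase(2 * pi * ref_freq * t))
  env_stab <- bc$transformed - min(bc$transformed)  # nonnegative for binning
  amp_mod <- amplitude_modulation_psi(env_stab, phi, n_bins = config$hist_bins)

  out <- block_metrics(prof, amp_mod = amp_mod, lambda = bc$lambda)
  out <- mutate(out,
                block_id = rec$block_id, condition = rec$condition,
                stim_freq = rec$stim_freq, peak_freq = peak, .before = 1)
  if (keep_profile) out$profile <- list(prof)
  out
}

#' Analyse a full multi-block experiment
#'
#' Applies [analyze_block()] to every non-initial recording and summarises
#' per condition against the sham baseline.
#'
#' @param recordings named list of [tremor_recording()]s (an `initial` entry
#'   is skipped for the condition summary but analysed if present).
#' @param config a [tremor_config()].
#' @param subject_id optional label carried into the outputs.
#' @return list with `blocks` (per-block metrics tibble) and `summary`
#'   (the [condition_summary()] tibble).
#' @export
analyze_experiment <- function(recordings, config = tremor_config(),
                               subject_id = NULL) {
  stopifnot(is.list(recordings), length(recordings) > 0L)
  blocks <- list_rbind(map(recordings, analyze_block, config = config))
  if (!is.null(subject_id)) blocks <- mutate(blocks, subject_id = subject_id, .before = 1)
  list(blocks = blocks,
       summary = condition_summary(filter(blocks, .data$condition != "initial")))
}
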