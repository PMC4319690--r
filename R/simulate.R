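#' Tremor generator parameters
#'
#' Parameters of the stochastic phase-oscillator model of physiological
#' tremor. The tremor is a Kuramoto-style forced oscillator: its phase
#' advances at base frequency `f0`, diffuses with intensity `freq_jitter_sd`
#' (units Hz * s^-1/2, so slow drifts in phase alignment accumulate over a
#' block), and is pulled toward the stimulation phase with dimensionless gain
#' `kappa`. The amplitude envelope is a positivity-reflected
#' Ornstein-Uhlenbeck process (mean `env_mean`, relaxation time `env_tau_s`,
#' stationary SD `env_sd`), which gives the right-skewed positive amplitudes
#' the Box-Cox stage expects. The scalar oscillation is projected onto the
#' three accelerometer axes through the unit vector `axis_vector`, with
#' additive white sensor noise `noise_sd` per axis.
#'
#' @param f0 tremor base frequency, Hz.
#' @param freq_jitter_sd phase-diffusion intensity, Hz * s^-1/2.
#' @param kappa phase-coupling gain to the stimulation phase (>= 0).
#' @param env_mean,env_tau_s,env_sd envelope OU parameters (arbitrary
#'   acceleration units / seconds).
#' @param axis_vector length-3 projection vector; normalised to unit length.
#' @param noise_sd additive white-noise SD per axis.
#' @param seed optional integer seed; the same seed reproduces the block
#'   bit-for-bit.
#' @return a list of class `tremor_params`.
#' @export
tremor_params <- function(f0 = 8.28, freq_jitter_sd = 0.05, kappa = 0,
                          env_mean = 1, env_tau_s = 5, env_sd = 0.3,
                          axis_vector = c(2, 1, 1) / sqrt(6),
                          noise_sd = 0.05, seed = NULL) {
  check_number(f0, "f0", lower = .Machine$double.eps)
  check_number(freq_jitter_sd, "freq_jitter_sd", lower = 0)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop_tremor("`kappa` must be a single finite number >= 0.", "validation")
  }
  check_number(env_mean, "env_mean", lower = 0)
  check_number(env_tau_s, "env_tau_s", lower = .Machine$double.eps)
  check_number(env_sd, "env_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(axis_vector) || length(axis_vector) != 3L ||
      sqrt(sum(axis_vector^2)) < .Machine$double.eps) {
    stop_tremor("`axis_vector` must be a nonzero length-3 numeric vector.", "validation")
  }
  axis_vector <- axis_vector / sqrt(sum(axis_vector^2))
  check_number(seed, "seed", allow_null = TRUE)
  structure(
    list(f0 = f0, freq_jitter_sd = freq_jitter_sd, kappa = kappa,
         env_mean = env_mean, env_tau_s = env_tau_s, env_sd = env_sd,
         axis_vector = axis_vector, noise_sd = noise_sd, seed = seed),
    class = "tremor_params"
  )
}

#' Simulate the tACS stimulation waveform
#'
#' A sinusoid at `freq` with no direct-current offset and a linear amplitude
#' ramp from zero over `ramp_s` seconds. In the sham condition the amplitude
#' ramps back down over the following `ramp_s` seconds and stays zero for the
#' rest of the block. The steady-state peak-to-peak amplitude equals
#' `peak_to_peak` (default 2000 uA); any residual DC over the active portion
#' is removed so the time-average is zero.
#'
#' @param freq stimulation frequency, Hz.
#' @param duration_s block duration, seconds.
#' @param fs sampling rate, Hz; must be at least `4 * freq`.
#' @param peak_to_peak steady-state peak-to-peak amplitude, uA.
#' @param ramp_s ramp duration, seconds.
#' @param sham logical; ramp down after a further `ramp_s` seconds.
#' @return numeric vector of length `round(duration_s * fs)`, in uA.
#' @examples
#' x <- simulate_stim_waveform(8, duration_s = 60, fs = 256)
#' max(x) - min(x)
#' @export
simulate_stim_waveform <- function(freq, duration_s, fs, peak_to_peak = 2000,
                                   ramp_s = 10, sham = FALSE) {
  check_number(freq, "freq", lower = 0)
  check_number(duration_s, "duration_s", lower = .Machine$double.eps)
  check_number(fs, "fs", lower = .Machine$double.eps)
  check_number(peak_to_peak, "peak_to_peak", lower = 0)
  check_number(ramp_s, "ramp_s", lower = 0)
  if (freq > 0 && fs < 4 * freq) {
    stop_tremor(sprintf("fs = %g Hz undersamples a %g Hz waveform (need fs >= 4 freq).",
                        fs, freq), "sampling")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- if (ramp_s > 0) pmin(t / ramp_s, 1) else rep(1, n)
  if (sham && ramp_s > 0) {
    env <- pmin(env, pmax(0, 2 - t / ramp_s))
  }
  x <- (peak_to_peak / 2) * env * sin(2 * pi * freq * t)
  active <- env > 0
  if (any(active)) x[active] <- x[active] - mean(x[active])
  x
}

#' Simulate the photic stimulation pulse train
#'
#' Regular rectangular light pulses at the tremor frequency (the photic
#' control delivers flashes at the same frequency as the tACS).
#'
#' @param freq flash rate, Hz (> 0).
#' @param duration_s duration, seconds.
#' @param fs sampling rate, Hz.
#' @param duty pulse duty cycle, in (0, 0.1]; the default keeps the sampled
#'   duty under 10% after discretisation.
#' @return numeric 0/1 vector of length `round(duration_s * fs)`.
#' @export
simulate_photic_train <- function(freq, duration_s, fs, duty = 0.05) {
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0) {
    stop_tremor("`freq` must be > 0.", "validation")
  }
  check_number(duration_s, "duration_s", lower = .Machine$double.eps)
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (!is.numeric(duty) || duty <= 0 || duty > 0.1) {
    stop_tremor("`duty` must lie in (0, 0.1].", "validation")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase01 <- (t * freq) %% 1
  as.double(phase01 < duty)
}

# Euler-Maruyama integration of the forced phase oscillator and the
# reflected OU envelope. Sequential in t because of the sin(phi - theta)
# coupling term; plain R loop is fast enough at recording rates.
integrate_oscillator <- function(n, dt, f0, jitter, kappa, stim_phase,
                                 env_mean, env_tau, env_sd) {
  dW_theta <- rnorm(n - 1) * sqrt(dt)
  dW_env <- rnorm(n - 1) * sqrt(dt)
  theta <- numeric(n)
  env <- numeric(n)
  theta[1] <- runif(1, 0, 2 * pi)
  env[1] <- abs(env_mean + env_sd * rnorm(1))
  two_pi_f0_dt <- 2 * pi * f0 * dt
  two_pi_kappa_dt <- 2 * pi * kappa * dt
  sig_theta <- 2 * pi * jitter
  sig_env <- env_sd * sqrt(2 / env_tau)
  for (i in seq_len(n - 1)) {
    th <- theta[i]
    theta[i + 1] <- th + two_pi_f0_dt +
      two_pi_kappa_dt * sin(stim_phase[i] - th) +
      sig_theta * dW_theta[i]
    e <- env[i] + (env_mean - env[i]) * dt / env_tau + sig_env * dW_env[i]
    env[i + 1] <- abs(e)  # reflect at zero
  }
  list(theta = theta, env = env)
}

#' Simulate one tremor accelerometry block
#'
#' Integrates the forced stochastic phase oscillator
#' `d theta = 2 pi f0 dt + 2 pi kappa sin(phi_stim - theta) dt + 2 pi
#' freq_jitter_sd dW`, multiplies by the reflected-OU envelope, projects onto
#' the three accelerometer axes, and adds white sensor noise. The stimulation
#' (or photic) series is carried as an extra channel of the returned
#' recording, mirroring a shared-amplifier acquisition.
#'
#' @param params a [tremor_params()] (set `params$seed` for reproducibility).
#' @param stim optional list describing the forcing: `series` (numeric, same
#'   length as the block), `phase` (radians per sample) and `label`
#'   (channel name, `"stim"` or `"photic"`). `NULL` simulates an unstimulated
#'   block (a zero `stim` channel, no forcing).
#' @param duration_s,fs block duration (s) and sampling rate (Hz).
#' @param block_id,condition,stim_freq recording metadata.
#' @return a [tremor_recording()] with channels `acc_x`, `acc_y`, `acc_z` and
#'   the stimulation channel.
#' @examples
#' p <- tremor_params(f0 = 8, seed = 1)
#' rec <- simulate_tremor_block(p, duration_s = 10, fs = 128)
#' rec
#' @export
simulate_tremor_block <- function(params, stim = NULL, duration_s = 180, fs = 256,
                                  block_id = "b01", condition = "initial",
                                  stim_freq = NA_real_) {
  stopifnot(inherits(params, "tremor_params"))
  check_number(duration_s, "duration_s", lower = .Machine$double.eps)
  check_number(fs, "fs", lower = .Machine$double.eps)
  n <- round(duration_s * fs)
  stim_label <- "stim"
  if (is.null(stim)) {
    stim_series <- numeric(n)
    stim_phase <- numeric(n)
  } else {
    stim_series <- stim$series
    stim_phase <- stim$phase
    stim_label <- stim$label %||% "stim"
    if (length(stim_series) != n || length(stim_phase) != n) {
      stop_tremor("Stimulation series/phase must match the block length.", "validation")
    }
  }
  run <- function() {
    osc <- integrate_oscillator(
      n, 1 / fs, params$f0, params$freq_jitter_sd, params$kappa, stim_phase,
      params$env_mean, params$env_tau_s, params$env_sd
    )
    core <- osc$env * cos(osc$theta)
    acc <- outer(core, params$axis_vector) +
      matrix(rnorm(3 * n, sd = params$noise_sd), n, 3)
    acc
  }
  acc <- if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
  data <- tibble(
    time = (seq_len(n) - 1) / fs,
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3]
  )
  data[[stim_label]] <- stim_series
  tremor_recording(data, fs = fs, block_id = block_id, condition = condition,
                   stim_freq = stim_freq, duration_s = duration_s)
}

#' Draw subject peak tremor frequencies
#'
#' Frequencies are drawn from Normal(8.28, 1.52^2) Hz truncated to
#' \[4, 14\] Hz, matching the group distribution of peak physiological tremor
#' (mean 8.28 Hz; group SD recovered from the reported SEM 0.44 Hz at
#' N = 12).
#'
#' @param n number of subjects.
#' @param mean,sd,lo,hi distribution parameters.
#' @return numeric vector of length `n`.
#' @export
draw_subject_f0 <- function(n, mean = 8.28, sd = 0.44 * sqrt(12), lo = 4, hi = 14) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a full experiment for one subject
#'
#' Generates one stimulation-free `initial` recording (360 s by default) plus
#' the 12 condition blocks (180 s each) of the two-cycle interleaved design,
#' with a caller-supplied mapping from condition to coupling gain kappa. The
#' stimulation frequency is the subject's tremor frequency rounded to 0.1 Hz,
#' as in the protocol. Sham blocks receive the ramp-down waveform and, through
#' the kappa map, no coupling.
#'
#' @param params a [tremor_params()] for the subject; `params$seed` seeds the
#'   whole session (per-block seeds are derived from it).
#' @param design a [block_design()] tibble; defaults to a seeded two-cycle
#'   design at `round(params$f0, 1)` Hz.
#' @param kappa_map named vector mapping conditions to kappa. Defaults couple
#'   only the right-shoulder montage strongly and photic more weakly.
#' @param block_duration_s,initial_duration_s,fs timing parameters.
#' @param peak_to_peak,ramp_s stimulation waveform parameters (uA, s).
#' @return list with `recordings` (named list of 13 [tremor_recording()]s)
#'   and `truth` (tibble of per-block ground truth: condition, kappa, f0,
#'   seed, stim_freq).
#' @examples
#' \donttest{
#' exp <- generate_experiment(tremor_params(f0 = 8, seed = 7),
#'                            block_duration_s = 20, initial_duration_s = 40,
#'                            fs = 128)
#' exp$truth
#' }
#' @export
generate_experiment <- function(params,
                                design = NULL,
                                kappa_map = c(FO = 0, cM1 = 0, LSh = 0,
                                              RSh = 0.1, sham = 0, photic = 0.05),
                                block_duration_s = 180,
                                initial_duration_s = 360,
                                fs = 256,
                                peak_to_peak = 2000,
                                ramp_s = 10) {
  stopifnot(inherits(params, "tremor_params"))
  base_seed <- params$seed %||% 1L
  stim_freq <- floor(params$f0 / 0.1 + 0.5) * 0.1
  if (is.null(design)) {
    design <- block_design("s01", stim_freq = stim_freq, seed = base_seed)
  }
  validate_block_design(design)
  missing <- setdiff(unique(design$condition), names(kappa_map))
  if (length(missing)) {
    stop_tremor(sprintf("kappa_map lacks condition(s): %s.",
                        paste(missing, collapse = ", ")), "validation")
  }

  block_params <- function(kappa, seed) {
    p <- params
    p$kappa <- kappa
    p$seed <- (base_seed * 1000L + seed) %% .Machine$integer.max
    class(p) <- "tremor_params"
    p
  }

  recs <- vector("list", nrow(design) + 1L)
  names(recs) <- c("initial", design$block_id)
  truth <- vector("list", nrow(design) + 1L)

  p0 <- block_params(0, 0L)
  recs[["initial"]] <- simulate_tremor_block(
    p0, stim = NULL, duration_s = initial_duration_s, fs = fs,
    block_id = "initial", condition = "initial", stim_freq = NA_real_
  )
  truth[[1]] <- tibble(block_id = "initial", condition = "initial",
                       kappa = 0, f0 = params$f0, seed = p0$seed,
                       stim_freq = NA_real_)

  n <- round(block_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    f <- design$stim_freq[i]
    kappa <- unname(kappa_map[[cond]])
    if (cond == "photic") {
      series <- simulate_photic_train(f, block_duration_s, fs)
      label <- "photic"
    } else {
      series <- simulate_stim_waveform(f, block_duration_s, fs,
                                       peak_to_peak = peak_to_peak,
                                       ramp_s = ramp_s, sham = cond == "sham")
      label <- "stim"
    }
    stim <- list(series = series, phase = wrap_phase(2 * pi * f * t), label = label)
    p <- block_params(kappa, i)
    recs[[design$block_id[i]]] <- simulate_tremor_block(
      p, stim = stim, duration_s = block_duration_s, fs = fs,
      block_id = design$block_id[i], condition = cond, stim_freq = f
    )
    truth[[i + 1L]] <- tibble(block_id = design$block_id[i], condition = cond,
                              kappa = kappa, f0 = params$f0, seed = p$seed,
                              stim_freq = f)
  }
  list(recordings = recs, truth = list_rbind(truth), design = design)
}
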