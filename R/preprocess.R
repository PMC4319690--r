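#' First principal component of multi-channel accelerometry
#'
#' Projects the mean-centred channels onto the leading eigenvector of their
#' covariance, so the plane of maximal tremor power is analysed regardless of
#' sensor orientation. The loading vector is unit-norm with its
#' largest-magnitude element positive (a deterministic sign convention).
#'
#' @param rec a [tremor_recording()] or a numeric matrix (samples x channels).
#' @param channels channel subset when `rec` is a recording; defaults to the
#'   `acc_*` channels.
#' @return list of class `pc_projection` with `series` (the projected
#'   univariate signal), `loading` (named unit vector) and `var_explained`.
#' @export
first_principal_component <- function(rec, channels = NULL) {
  x <- if (inherits(rec, "tremor_recording")) {
    recording_channels(rec, channels)
  } else {
    as.matrix(rec)
  }
  if (ncol(x) < 2L) {
    stop_tremor("Need at least 2 channels for a principal component.", "validation")
  }
  v <- apply(x, 2, var)
  if (any(v <= .Machine$double.eps)) {
    stop_tremor("Zero-variance channel(s); principal component is degenerate.",
                "degenerate")
  }
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(cov(xc), symmetric = TRUE)
  w <- eg$vectors[, 1L]
  if (w[which.max(abs(w))] < 0) w <- -w
  names(w) <- colnames(x)
  structure(
    list(series = drop(xc %*% w), loading = w,
         var_explained = eg$values[1L] / sum(eg$values)),
    class = "pc_projection"
  )
}

# --- DPSS (discrete prolate spheroidal) tapers -------------------------------
#
# Eigenvectors of the classical symmetric tridiagonal matrix whose spectrum
# orders tapers by spectral concentration. Exact dense solve up to n = 1024;
# longer tapers are computed at the base length and spline-interpolated onto
# the target grid, then re-normalised (the usual large-n construction).
dpss_tapers <- function(n, k, nw) {
  key <- sprintf("dpss_%d_%d_%g", n, k, nw)
  cached <- the[[key]]
  if (!is.null(cached)) return(cached)
  base_n <- min(n, 1024L)
  base_key <- sprintf("dpss_%d_%d_%g", base_n, k, nw)
  tap <- the[[base_key]]
  if (is.null(tap)) {
    tap <- dpss_exact(base_n, k, nw)
    the[[base_key]] <- tap
  }
  if (base_n < n) {
    x0 <- seq(0, 1, length.out = base_n)
    x1 <- seq(0, 1, length.out = n)
    tap <- apply(tap, 2, function(v) spline(x0, v, xout = x1)$y)
    tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  }
  the[[key]] <- tap
  tap
}

dpss_exact <- function(n, k, nw) {
  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tap[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    tap[, j] <- v
  }
  tap
}

#' Thomson multitaper power spectral density
#'
#' Averages eigenspectra over `n_tapers` discrete prolate spheroidal tapers
#' with time-bandwidth product `nw` (default `(K + 1) / 2`, the standard
#' `K = 2NW - 1` relation for the paper-specified K = 12). The effective
#' spectral resolution is `2 NW / duration` Hz.
#'
#' @param x univariate numeric series (length >= `2 * fs`).
#' @param fs sampling rate, Hz.
#' @param n_tapers number of tapers K (default 12).
#' @param nw time-bandwidth product NW; `NULL` gives `(K + 1) / 2`.
#' @param nfft FFT length; defaults to the next 2-3-5-smooth number >= n.
#' @return tibble of class `spectral_estimate` with columns `freq` (Hz) and
#'   `power` (one-sided PSD), and attributes `n_tapers`, `nw`,
#'   `resolution_hz`, `fs`.
#' @examples
#' t <- seq(0, 20, by = 1 / 64)[-1]
#' est <- multitaper_psd(sin(2 * pi * 8 * t) + rnorm(length(t), sd = 0.2), fs = 64)
#' detect_peak_frequency(est)
#' @export
multitaper_psd <- function(x, fs, n_tapers = 12, nw = NULL, nfft = NULL) {
  n <- length(x)
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (n < 2 * fs) {
    stop_tremor("Series must be at least 2 s long for a multitaper estimate.",
                "length")
  }
  n_tapers <- as.integer(n_tapers)
  if (n_tapers < 1L) stop_tremor("n_tapers must be >= 1.", "validation")
  nw <- nw %||% ((n_tapers + 1) / 2)
  nfft <- as.integer(nfft %||% stats::nextn(n, c(2, 3, 5)))
  x <- x - mean(x)
  tap <- dpss_tapers(n, n_tapers, nw)
  nfreq <- nfft %/% 2L + 1L
  acc <- numeric(nfreq)
  for (j in seq_len(n_tapers)) {
    xt <- c(x * tap[, j], numeric(nfft - n))
    X <- fft(xt)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / fs
  }
  power <- acc / n_tapers
  # one-sided: double everything except DC (and Nyquist when nfft is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nfreq] <- 1
  power <- power * dbl
  out <- tibble(freq = (seq_len(nfreq) - 1) * fs / nfft, power = power)
  structure(out,
            class = c("spectral_estimate", class(out)),
            n_tapers = n_tapers, nw = nw,
            resolution_hz = 2 * nw / (n / fs), fs = fs)
}

#' Detect the peak tremor frequency from a spectral estimate
#'
#' Argmax of power within a physiological search band, rounded to the nearest
#' `round_to` Hz (the protocol matches stimulation to the tremor peak to the
#' nearest 0.1 Hz). Ties break toward the lower frequency.
#'
#' @param est a `spectral_estimate` from [multitaper_psd()], or any data frame
#'   with `freq` and `power` columns.
#' @param band length-2 search band in Hz (default 4-14 Hz, the physiological
#'   tremor range).
#' @param round_to rounding grid in Hz; 0 disables rounding.
#' @return peak frequency in Hz.
#' @export
detect_peak_frequency <- function(est, band = c(4, 14), round_to = 0.1) {
  stopifnot(is.data.frame(est), all(c("freq", "power") %in% names(est)))
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2]) {
    stop_tremor("`band` must be an increasing frequency pair.", "validation")
  }
  sel <- est$freq >= band[1] & est$freq <= band[2]
  if (!any(sel)) stop_tremor("Search band contains no frequency bins.", "validation")
  f <- est$freq[sel]
  p <- est$power[sel]
  peak <- f[which.max(p)]  # first maximum = lowest frequency on ties
  if (round_to > 0) peak <- floor(peak / round_to + 0.5) * round_to
  peak
}

#' Zero-phase Butterworth band-pass filter
#'
#' Cascades a third-order high-pass at `center - half_width` and a
#' third-order low-pass at `center + half_width`, each applied forward and
#' backward (so the net phase response is zero and the magnitude response is
#' squared). Cutoffs are applied as designed, without compensating the
#' squared response's -3 dB points.
#'
#' @param x univariate numeric series.
#' @param fs sampling rate, Hz.
#' @param center passband centre, Hz.
#' @param half_width half of the passband, Hz (default 1, i.e. a 2 Hz band).
#' @param order filter order for each of the two filters (default 3).
#' @return filtered series, same length as `x`.
#' @seealso [bandpass_gain()] for the analytic net amplitude response.
#' @export
zero_phase_bandpass <- function(x, fs, center, half_width = 1, order = 3) {
  check_number(center, "center", lower = .Machine$double.eps)
  check_number(half_width, "half_width", lower = .Machine$double.eps)
  check_number(order, "order", lower = 1)
  lo <- center - half_width
  hi <- center + half_width
  if (lo <= 0 || hi >= fs / 2) {
    stop_tremor(sprintf("Cutoffs (%g, %g) Hz must lie inside (0, fs/2).", lo, hi),
                "validation")
  }
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}

#' Analytic net amplitude gain of the zero-phase band-pass
#'
#' Net amplitude response of the forward-backward cascade used by
#' [zero_phase_bandpass()]: the product of the squared magnitude responses of
#' the two digital Butterworth filters (evaluated from their designed
#' coefficients), which is also the factor by which a steady sinusoid at
#' frequency `f` is scaled.
#'
#' @param f frequency (Hz), vectorised.
#' @param fs sampling rate, Hz.
#' @param center,half_width,order as in [zero_phase_bandpass()].
#' @return numeric vector of amplitude gains.
#' @export
bandpass_gain <- function(f, fs, center, half_width = 1, order = 3) {
  hp <- signal::butter(order, (center - half_width) / (fs / 2), type = "high")
  lp <- signal::butter(order, (center + half_width) / (fs / 2), type = "low")
  gain1 <- function(filt, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(vapply(z, function(zz) {
      sum(filt$b * zz^(seq_along(filt$b) - 1)) /
        sum(filt$a * zz^(seq_along(filt$a) - 1))
    }, complex(1)))
  }
  (gain1(hp, f)^2) * (gain1(lp, f)^2)
}

#' Decimate a series to a lower sampling rate
#'
#' Anti-aliased integer-factor decimation (8th-order Chebyshev low-pass via
#' `signal::decimate`). Used optionally to reduce 2048 Hz recordings to
#' analysis rate before the PSI pipeline.
#'
#' @param x numeric series.
#' @param fs current sampling rate, Hz.
#' @param to_hz target rate; `fs / to_hz` must be a positive integer.
#' @return list with `series` and `fs`.
#' @export
decimate_series <- function(x, fs, to_hz) {
  q <- fs / to_hz
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    stop_tremor("fs / to_hz must be a positive integer.", "validation")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(list(series = x, fs = fs))
  list(series = signal::decimate(x, q), fs = to_hz)
}
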