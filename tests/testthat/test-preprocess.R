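test_that("principal component recovers a known single source and mixing", {
  set.seed(2)
  n <- 4000
  s <- sin(2 * pi * 8 * (1:n) / 256) * (1 + 0.2 * rnorm(n))
  # near-degenerate case: one active axis
  x1 <- cbind(s, rnorm(n, sd = 1e-3), rnorm(n, sd = 1e-3))
  pc1 <- first_principal_component(x1)
  expect_gt(abs(cor(pc1$series, s)), 0.999)

  # known mixing vector recovered within 2 degrees
  a <- c(0.6, 0.7, 0.4)
  a <- a / sqrt(sum(a^2))
  x2 <- outer(s, a) + matrix(rnorm(3 * n, sd = 0.02), n, 3)
  pc2 <- first_principal_component(x2)
  angle <- acos(min(1, abs(sum(pc2$loading * a)))) * 180 / pi
  expect_lt(angle, 2)
  expect_equal(sum(pc2$loading^2), 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  expect_gt(pc2$loading[which.max(abs(pc2$loading))], 0)

  # PCA output variance is at least any single centred channel's variance
  expect_gte(var(pc2$series) + 1e-12, max(apply(x2, 2, var)))

  expect_error(first_principal_component(cbind(rep(1, 100), rnorm(100))),
               class = "tremorlock_error_degenerate")
  expect_error(first_principal_component(matrix(rnorm(100), ncol = 1)),
               class = "tremorlock_error_validation")
})

test_that("multitaper spectrum finds a sinusoid where the periodogram does", {
  set.seed(3)
  fs <- 128
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t) + rnorm(length(t), sd = 0.1)
  est <- multitaper_psd(x, fs)
  # peak within one resolution bandwidth of 8 Hz
  peak_raw <- est$freq[which.max(est$power)]
  expect_lt(abs(peak_raw - 8), attr(est, "resolution_hz"))
  # independent plain-periodogram oracle
  xp <- x - mean(x)
  P <- Mod(fft(xp))^2
  freqs <- (seq_along(P) - 1) * fs / length(P)
  half <- freqs <= fs / 2
  oracle_peak <- freqs[half][which.max(P[half])]
  expect_lt(abs(peak_raw - oracle_peak), attr(est, "resolution_hz"))
})

test_that("K = 1 multitaper equals the single tapered periodogram", {
  set.seed(4)
  fs <- 64
  x <- rnorm(10 * fs)
  est <- multitaper_psd(x, fs, n_tapers = 1, nw = 1)
  tap <- tremorlock:::dpss_tapers(length(x), 1, 1)
  nfft <- stats::nextn(length(x), c(2, 3, 5))
  xt <- c((x - mean(x)) * tap[, 1], numeric(nfft - length(x)))
  ref <- Mod(fft(xt)[seq_len(nfft %/% 2 + 1)])^2 / fs
  dbl <- rep(2, nfft %/% 2 + 1)
  dbl[c(1, nfft %/% 2 + 1)] <- 1
  expect_equal(est$power, ref * dbl, tolerance = 1e-12)
})

test_that("multitaper power integrates to the variance and stays flat on noise", {
  set.seed(5)
  ok <- 0
  for (i in 1:5) {
    x <- rnorm(30 * 128)
    est <- multitaper_psd(x, 128)
    df <- est$freq[2] - est$freq[1]
    expect_equal(sum(est$power) * df, var(x), tolerance = 0.1)
    band <- est$power[est$freq >= 1 & est$freq <= 20]
    if (max(band) <= 5 * median(band)) ok <- ok + 1
  }
  expect_gte(ok, 4)
  expect_error(multitaper_psd(rnorm(100), fs = 128),
               class = "tremorlock_error_length")
})

test_that("peak detection rounds to 0.1 Hz and breaks ties downward", {
  est <- tibble::tibble(freq = seq(0, 20, by = 0.01),
                        power = stats::dnorm(seq(0, 20, by = 0.01), 8.23, 0.2))
  expect_equal(detect_peak_frequency(est), 8.2)
  est2 <- tibble::tibble(freq = c(5, 6, 7, 8, 9),
                         power = c(0, 1, 0.5, 1, 0))
  expect_equal(detect_peak_frequency(est2, band = c(5, 9)), 6.0)
  expect_error(detect_peak_frequency(est, band = c(30, 40)),
               class = "tremorlock_error_validation")
})

test_that("zero-phase band-pass matches its analytic response with zero lag", {
  fs <- 256
  t <- (0:(40 * fs - 1)) / fs
  mid <- seq(10 * fs, 30 * fs)
  gains <- sapply(c(8, 16), function(f) {
    y <- zero_phase_bandpass(sin(2 * pi * f * t), fs, center = 8)
    sd(y[mid]) / sd(sin(2 * pi * f * t)[mid])
  })
  # independent oracle: closed-form squared magnitude of the designed
  # forward-backward Butterworth cascade
  expected <- bandpass_gain(c(8, 16), fs, center = 8)
  expect_equal(gains, expected, tolerance = 0.02)
  expect_lt(gains[2], 0.05)

  # zero net phase: cross-correlation peak at lag 0
  y8 <- zero_phase_bandpass(sin(2 * pi * 8 * t), fs, 8)
  cc <- stats::ccf(y8[mid], sin(2 * pi * 8 * t)[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # filtering commutes with time reversal away from the edge transients
  # (the pipeline always discards the trimmed edges)
  set.seed(6)
  x <- rnorm(10 * fs)
  core <- seq(2 * fs, length(x) - 2 * fs)
  expect_equal(rev(zero_phase_bandpass(rev(x), fs, 8))[core],
               zero_phase_bandpass(x, fs, 8)[core], tolerance = 1e-6)

  expect_error(zero_phase_bandpass(x, fs, center = 0.5),
               class = "tremorlock_error_validation")
  expect_error(zero_phase_bandpass(x, fs, center = 127.6),
               class = "tremorlock_error_validation")
})

test_that("decimation preserves the band of interest", {
  fs <- 1024
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t)
  d <- decimate_series(x, fs, 256)
  expect_equal(d$fs, 256)
  expect_length(d$series, length(x) / 4)
  mid <- seq(256, length(d$series) - 256)
  expect_equal(sd(d$series[mid]) * sqrt(2), 1, tolerance = 0.02)
  expect_error(decimate_series(x, fs, 300), class = "tremorlock_error_validation")
})
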