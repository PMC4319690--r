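test_that("analytic signal recovers envelope and instantaneous frequency", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  a <- analytic_signal(cos(2 * pi * 8 * t), fs)
  inner <- seq(2 * fs, length(t) - 2 * fs)
  expect_true(all(abs(a$envelope[inner] - 1) < 0.01))
  inst <- instantaneous_frequency(a)
  expect_equal(mean(inst[inner]), 8, tolerance = 0.01)

  a2 <- analytic_signal(0.5 * cos(2 * pi * 8 * t), fs)
  expect_true(all(abs(a2$envelope[inner] - 0.5) < 0.005))

  # linear chirp 6 -> 10 Hz: instantaneous frequency tracks the chirp law
  dur <- 20
  f_inst <- 6 + 4 * t / dur
  chirp <- cos(2 * pi * (6 * t + 2 * t^2 / dur))
  a3 <- analytic_signal(chirp, fs)
  inst3 <- instantaneous_frequency(a3)
  mid <- seq(5 * fs, 15 * fs)
  expect_lt(max(abs(inst3[mid] - f_inst[mid])), 0.1)

  expect_error(analytic_signal(rep(1, 10 * fs), fs),
               class = "tremorlock_error_degenerate")
  expect_error(analytic_signal(rnorm(3 * fs), fs),
               class = "tremorlock_error_length")
})

test_that("Box-Cox maximum likelihood recovers known transforms", {
  set.seed(7)
  x_log <- exp(rnorm(1e4))
  bc <- boxcox_stabilize(x_log)
  expect_lt(abs(bc$lambda), 0.1)

  x_norm <- rnorm(1e4, 10, 1)
  bc2 <- boxcox_stabilize(x_norm)
  expect_gt(bc2$lambda, 0.7)
  expect_lt(bc2$lambda, 1.3)

  # cross-check against the standard profile-likelihood implementation
  skip_if_not_installed("MASS")
  y <- x_log[1:2000]
  prof <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lambda_mass <- prof$x[which.max(prof$y)]
  expect_equal(boxcox_stabilize(y)$lambda, lambda_mass, tolerance = 0.02)

  expect_error(boxcox_stabilize(c(1, 0, 2)), class = "tremorlock_error_domain")
  expect_equal(boxcox_stabilize(c(1, 0, 2) , shift = 0.5)$shift, 0.5)
})

test_that("Box-Cox decouples rolling mean and spread of multiplicative envelopes", {
  set.seed(8)
  roll_stat <- function(x, w, f) {
    idx <- seq(1, length(x) - w, by = w)
    vapply(idx, function(i) f(x[i:(i + w - 1)]), numeric(1))
  }
  deltas <- replicate(20, {
    e <- exp(as.numeric(stats::filter(rnorm(4000, sd = 0.6), rep(1, 50) / 7,
                                      method = "convolution", sides = 2)))
    e <- e[!is.na(e)]
    bc <- boxcox_stabilize(e)
    cor_raw <- cor(roll_stat(e, 50, mean), roll_stat(e, 50, sd),
                   method = "spearman")
    cor_bc <- cor(roll_stat(bc$transformed, 50, mean),
                  roll_stat(bc$transformed, 50, sd), method = "spearman")
    abs(cor_raw) - abs(cor_bc)
  })
  expect_gt(median(deltas), 0)
})

test_that("phase differences wrap into (-pi, pi]", {
  expect_equal(phase_difference(0.1, -0.1), 0.2)
  expect_equal(phase_difference(3.0, -3.0), 6.0 - 2 * pi)
  x <- runif(50, -pi, pi)
  expect_equal(phase_difference(x, x), rep(0, 50))
  expect_true(all(phase_difference(runif(100, -10, 10), runif(100, -10, 10)) > -pi))
  expect_true(all(phase_difference(runif(100, -10, 10), runif(100, -10, 10)) <= pi))
  expect_error(phase_difference(1:3, 1:4), class = "tremorlock_error_validation")
})

test_that("PSI attains its analytic bounds and rotation invariance", {
  expect_equal(psi(rep(0.7, 1000)), 1.0)
  expect_lt(psi(seq(0, 2 * pi, length.out = 361)[-361]), 1e-12)
  expect_equal(psi(c(0, pi / 2)), sqrt(2) / 2)
  set.seed(9)
  phi <- runif(500, -pi, pi)
  expect_equal(psi(phi), psi(phi + 1.234), tolerance = 1e-12)
  expect_error(psi(numeric(0)), class = "tremorlock_error_validation")
})

test_that("PSI of uniform random phases follows the Rayleigh small-sample law", {
  set.seed(10)
  n <- 1000
  vals <- replicate(400, psi(runif(n, -pi, pi)))
  expect_equal(mean(vals), sqrt(pi) / 2 / sqrt(n), tolerance = 0.1)
})

test_that("phase histograms are normalised probability distributions", {
  h <- phase_histogram(seq(-pi + 1e-9, pi, length.out = 2000), n_bins = 20)
  expect_equal(nrow(h), 20L)
  expect_true(all(abs(h$prob - 0.05) < 0.005))
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  h2 <- phase_histogram(rep(0.1, 50), n_bins = 20)
  expect_equal(max(h2$prob), 1)
  expect_equal(sum(h2$prob > 0), 1L)
  set.seed(11)
  expect_equal(sum(phase_histogram(rnorm(500))$prob), 1, tolerance = 1e-12)
  expect_error(phase_histogram(1:5, n_bins = 1),
               class = "tremorlock_error_validation")
})

test_that("amplitude-modulation PSI quantifies phase-locked amplitude", {
  phi <- seq(-pi + 1e-6, pi, length.out = 20000)
  env <- 1 + cos(phi)
  expect_equal(amplitude_modulation_psi(env, phi), 0.5, tolerance = 0.01)
  expect_lt(amplitude_modulation_psi(rep(2, 20000), phi), 1e-12)
  # phase-independent envelope sits inside the permutation null
  set.seed(12)
  env_r <- abs(rnorm(2000, 1, 0.3))
  phi_r <- runif(2000, -pi, pi)
  obs <- amplitude_modulation_psi(env_r, phi_r)
  null <- replicate(200, amplitude_modulation_psi(sample(env_r), phi_r))
  expect_lt(obs, quantile(null, 0.95) * 1.5)
  expect_error(amplitude_modulation_psi(numeric(10), runif(10)),
               class = "tremorlock_error_degenerate")
})

test_that("stability profiles span the 0-20 Hz grid and smoothing never raises the max", {
  rec <- quick_block(kappa = 0.2, seed = 21, duration_s = 30)
  pc <- first_principal_component(rec)
  filt <- zero_phase_bandpass(pc$series, rec$fs, 8)
  prof <- stability_profile(filt[seq(2 * rec$fs, length(filt) - 2 * rec$fs)],
                            rec$fs)
  expect_equal(nrow(prof), 201L)
  expect_equal(prof$freq[1], 0)
  expect_equal(prof$freq[201], 20)
  expect_true(all(prof$psi >= 0 & prof$psi <= 1))
  expect_lte(max(prof$psi), max(prof$psi_raw))
  expect_error(stability_profile(filt, rec$fs, step = 0),
               class = "tremorlock_error_validation")
})

test_that("coupled blocks out-score white-noise-phase input on the raw profile", {
  set.seed(19)
  for (seed in 1:5) {
    rec <- quick_block(kappa = 0.2, seed = seed, duration_s = 60)
    pc <- first_principal_component(rec)
    filt <- zero_phase_bandpass(pc$series, rec$fs, 8)
    keep <- seq(2 * rec$fs, length(filt) - 2 * rec$fs)
    prof_c <- stability_profile(filt[keep], rec$fs)
    noise <- zero_phase_bandpass(rnorm(length(pc$series)), rec$fs, 8)
    prof_u <- stability_profile(noise[keep], rec$fs)
    expect_gt(max(prof_c$psi_raw), max(prof_u$psi_raw))
  }
})

test_that("block metrics pick the profile maximum with downward tie-breaks", {
  prof <- tibble::tibble(freq = seq(0, 20, 0.1),
                         psi = 0.1, psi_raw = 0.1)
  prof$psi[80] <- 0.62  # 7.9 Hz
  m <- block_metrics(prof, amp_mod = 0.3, lambda = 0.2)
  expect_equal(m$max_psi, 0.62)
  expect_equal(m$argmax_freq, 7.9)
  expect_equal(m$amp_mod_psi, 0.3)

  flat <- tibble::tibble(freq = seq(0, 20, 0.1), psi = 0.1, psi_raw = 0.1)
  expect_equal(block_metrics(flat)$argmax_freq, 0)

  bad <- flat
  bad$psi[5] <- 1.5
  expect_error(block_metrics(bad), class = "tremorlock_error_validation")
})

test_that("condition summaries express change against the sham baseline", {
  metrics <- tibble::tibble(
    condition = c("RSh", "RSh", "sham", "sham"),
    max_psi = c(0.60, 0.56, 0.52, 0.48),
    amp_mod_psi = c(0.2, 0.3, 0.1, 0.1)
  )
  s <- condition_summary(metrics)
  rsh <- s[s$condition == "RSh", ]
  expect_equal(rsh$mean_max_psi, 0.58)
  expect_equal(rsh$sham_baseline, 0.50)
  expect_equal(rsh$pct_change, 16.0)
  expect_equal(s$pct_change[s$condition == "sham"], 0)

  same <- tibble::tibble(condition = c("FO", "sham"), max_psi = c(0.5, 0.5))
  expect_equal(condition_summary(same)$pct_change, c(0, 0))

  zero <- tibble::tibble(condition = c("FO", "sham"), max_psi = c(0.5, 0))
  expect_error(condition_summary(zero), class = "tremorlock_error_degenerate")
  nosham <- tibble::tibble(condition = "FO", max_psi = 0.5)
  expect_error(condition_summary(nosham), class = "tremorlock_error_validation")
})
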