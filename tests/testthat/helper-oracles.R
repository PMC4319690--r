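# Independent oracles and small fixtures shared across tests.

# Legendre polynomial P_l(x) by the three-term recurrence.
legendre_p <- function(l, x) {
  p0 <- rep(1, length(x))
  if (l == 0) return(p0)
  p1 <- x
  if (l >= 2) {
    for (k in 2:l) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1
      p1 <- p2
    }
  }
  p1
}

# Analytic potential of a two-shell concentric sphere (inner radius a,
# conductivity s1; shell to radius b, conductivity s2) with point current
# +I/-I at the poles of the outer surface. Azimuthally symmetric Legendre
# series, odd terms only; solved per degree in a scaled basis for
# conditioning. r in metres, costh = cos(theta).
two_shell_potential <- function(r, costh, a, b, s1, s2, I, lmax = 299) {
  alpha <- a / b
  rho <- r / b
  out <- numeric(length(costh))
  for (l in seq(1, lmax, by = 2)) {
    f_l <- (2 * l + 1) * I / (2 * pi * b^2)
    sol <- solve(
      rbind(c(l * (s2 - s1), -(s1 * l + s2 * (l + 1))),
            c(s2 * l, -s2 * (l + 1) * alpha^(2 * l + 1))),
      c(0, b * f_l)
    )
    C <- sol[1]
    q <- sol[2]
    val <- if (r <= a) (C + q) * rho^l else C * rho^l + q * alpha^(2 * l + 1) * rho^(-l - 1)
    out <- out + val * legendre_p(l, costh)
  }
  out
}

# Trilinear sample of a 3-D array at volume-centred mm coordinates.
trilinear_sample <- function(vol, p_mm, h_mm) {
  dims <- dim(vol)
  g <- (p_mm + dims * h_mm / 2) / h_mm + 0.5
  i0 <- floor(g)
  f <- g - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + w * vol[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

# Small homogeneous-cube model with full-face plate electrodes along z.
plate_cube <- function(n = 16, h_mm = 2, sigma = 0.33) {
  lab <- array(1L, dim = c(n, n, n))
  m <- voxel_model(lab, h_mm, tibble::tibble(label = 1L, tissue = "gray",
                                             sigma = sigma))
  hi <- array(FALSE, dim = c(n, n, n)); hi[, , n] <- TRUE
  lo <- array(FALSE, dim = c(n, n, n)); lo[, , 1] <- TRUE
  m |>
    electrode_from_mask(hi, "source", 1) |>
    electrode_from_mask(lo, "return", -1)
}

# A short coupled (or uncoupled) synthetic block at analysis rate.
quick_block <- function(kappa, seed, f0 = 8, duration_s = 60, fs = 256,
                        condition = "RSh") {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  stim <- list(series = simulate_stim_waveform(f0, duration_s, fs),
               phase = wrap_phase(2 * pi * f0 * t), label = "stim")
  p <- tremor_params(f0 = f0, kappa = kappa, seed = seed)
  simulate_tremor_block(p, stim, duration_s, fs, condition = condition,
                        stim_freq = f0)
}
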