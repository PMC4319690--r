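test_that("phantoms carry the reference conductivity table", {
  ph <- build_phantom(voxel_size_mm = 8)
  expect_s3_class(ph, "voxel_model")
  sig <- setNames(ph$tissues$sigma, ph$tissues$tissue)
  expect_equal(unname(sig["bone"]), 0.0064)
  expect_equal(unname(sig["csf"]), 1.79)
  expect_equal(unname(sig["skin"]), 0.43)
  expect_equal(unname(sig["gray"]), 0.33)
  expect_equal(unname(sig["white"]), 0.142)
  expect_equal(unname(sig["air"]), 1e-4)
  # bone voxels exist and map to the bone conductivity
  bone_lbl <- ph$tissues$label[ph$tissues$tissue == "bone"]
  expect_true(any(ph$labels == bone_lbl))
  expect_equal(unique(ph$sigma[ph$labels == bone_lbl]), 0.0064)
  # all outer faces are air
  d <- dim(ph$labels)
  expect_true(all(ph$labels[c(1, d[1]), , ] == 0))
  expect_true(all(ph$labels[, c(1, d[2]), ] == 0))
  expect_true(all(ph$labels[, , c(1, d[3])] == 0))

  sh <- build_phantom(voxel_size_mm = 8, shoulders = TRUE)
  avg_lbl <- sh$tissues$label[sh$tissues$tissue == "average"]
  expect_true(any(sh$labels == avg_lbl))
  expect_equal(unique(sh$sigma[sh$labels == avg_lbl]), 0.08)

  expect_error(build_phantom(layers = list(skin = c(50, 50, 50),
                                           bone = c(55, 45, 45)),
                             voxel_size_mm = 8),
               class = "tremorlock_error_validation")
})

test_that("electrode pads land on the surface with saline underlay", {
  ph <- build_phantom(voxel_size_mm = 2)
  ph2 <- attach_electrode(ph, c(0, 0), c(50, 70), "source", normal = "+z")
  el <- ph2$electrodes[[1]]
  h <- ph2$voxel_size_mm
  # footprint area within one voxel ring of 50 x 70 = 3500 mm^2
  area <- length(el$voxels) * h^2
  perimeter_ring <- 2 * (50 + 70) * h
  expect_lt(abs(area - 3500), perimeter_ring + 4 * h^2)
  sal_lbl <- ph2$tissues$label[ph2$tissues$tissue == "saline"]
  expect_equal(unique(ph2$sigma[ph2$labels == sal_lbl]), 0.367)
  expect_gt(length(el$saline_voxels), 0)

  # off-surface pad centre errors
  expect_error(attach_electrode(ph, c(500, 500), c(50, 70), "source"),
               class = "tremorlock_error_validation")
  # overlapping pads error
  expect_error(attach_electrode(ph2, c(0, 0), c(50, 70), "return",
                                normal = "+z"),
               class = "tremorlock_error_validation")
})

test_that("parallel-plate solution matches the analytic field within 1%", {
  m <- plate_cube(n = 16, h_mm = 2, sigma = 0.33)
  sol <- solve_laplace(m, tol = 1e-10)
  n <- 16
  h <- 2e-3
  E_true <- 2 / ((n - 1) * h)
  Emag <- sqrt(sol$E[[1]]^2 + sol$E[[2]]^2 + sol$E[[3]]^2)
  interior <- Emag[4:13, 4:13, 3:14]
  expect_true(all(abs(interior - E_true) / E_true < 0.01))
  # phi linear in the plate-normal coordinate
  expect_equal(diff(sol$phi[8, 8, ]), rep(2 / (n - 1), n - 1), tolerance = 1e-6)
  # Dirichlet voxels hold their potentials exactly
  expect_true(all(sol$phi[, , n] == 1))
  expect_true(all(sol$phi[, , 1] == -1))
})

test_that("two-layer slab keeps normal J continuous and splits E by conductivity", {
  n <- 16
  lab <- array(1L, dim = c(n, n, n))
  lab[, , (n / 2 + 1):n] <- 2L
  m <- voxel_model(lab, 2, tibble::tibble(label = c(1L, 2L),
                                          tissue = c("t1", "t2"),
                                          sigma = c(0.4, 0.2)))
  hi <- array(FALSE, dim = dim(lab)); hi[, , n] <- TRUE
  lo <- array(FALSE, dim = dim(lab)); lo[, , 1] <- TRUE
  m <- electrode_from_mask(m, hi, "source", 1)
  m <- electrode_from_mask(m, lo, "return", -1)
  sol <- solve_laplace(m, tol = 1e-11)
  jz1 <- sol$J[[3]][8, 8, 4]
  jz2 <- sol$J[[3]][8, 8, 12]
  expect_equal(jz1 / jz2, 1, tolerance = 0.01)        # normal J continuous
  ez1 <- sol$E[[3]][8, 8, 4]
  ez2 <- sol$E[[3]][8, 8, 12]
  expect_equal(ez2 / ez1, 2, tolerance = 0.01)        # |E| ratio 1:2
})

test_that("solutions obey conservation, reciprocity and linearity", {
  m <- plate_cube(n = 12, h_mm = 2)
  sol <- solve_laplace(m, tol = 1e-11)
  # closed surface containing no electrode carries no net current
  box <- array(FALSE, dim = dim(m$labels))
  box[4:9, 4:9, 4:9] <- TRUE
  expect_lt(abs(current_through(sol, box)) / sol$injected_current, 1e-8)

  # swapping the electrode potentials negates phi everywhere
  m_swap <- plate_cube(n = 12, h_mm = 2)
  m_swap$electrodes[[1]]$potential <- -1
  m_swap$electrodes[[2]]$potential <- 1
  sol_swap <- solve_laplace(m_swap, tol = 1e-11)
  expect_equal(sol_swap$phi, -sol$phi, tolerance = 1e-8)

  # doubling potentials doubles current and |J|
  m2 <- plate_cube(n = 12, h_mm = 2)
  m2$electrodes[[1]]$potential <- 2
  m2$electrodes[[2]]$potential <- -2
  sol2 <- solve_laplace(m2, tol = 1e-11)
  expect_equal(sol2$injected_current, 2 * sol$injected_current,
               tolerance = 1e-8)
  expect_equal(sol2$Jmag, 2 * sol$Jmag, tolerance = 1e-6)

  # solver reports non-convergence rather than returning garbage
  expect_error(solve_laplace(plate_cube(n = 12), tol = 1e-14, max_iter = 2L),
               class = "tremorlock_error_solver")
})

test_that("current scaling is exact and composes multiplicatively", {
  sol <- solve_laplace(plate_cube(n = 10), tol = 1e-10)
  s1 <- scale_to_current(sol)
  expect_identical(s1$injected_current, 1e-3)
  s_same <- scale_to_current(sol, target = sol$injected_current)
  expect_equal(s_same$phi, sol$phi, tolerance = 1e-12)
  s2 <- scale_to_current(scale_to_current(sol, 2e-3), 1e-3)
  expect_equal(s2$Jmag, s1$Jmag, tolerance = 1e-12)
  bad <- sol
  bad$injected_current <- 0
  expect_error(scale_to_current(bad), class = "tremorlock_error_degenerate")
})

test_that("ROI means and montage contrasts follow their definitions", {
  sol <- solve_laplace(plate_cube(n = 10), tol = 1e-10)
  mask1 <- array(FALSE, dim = dim(sol$phi)); mask1[4:6, 4:6, 4:6] <- TRUE
  mask2 <- array(FALSE, dim = dim(sol$phi)); mask2[7, 7, 7] <- TRUE
  m1 <- roi_mean_density(sol, mask1)
  m2 <- roi_mean_density(sol, mask2)
  expect_equal(m2, sol$Jmag[7, 7, 7])
  u <- roi_mean_density(sol, mask1 | mask2)
  w <- (sum(mask1) * m1 + sum(mask2) * m2) / (sum(mask1) + sum(mask2))
  expect_equal(u, w)
  expect_error(roi_mean_density(sol, array(FALSE, dim = dim(sol$phi))),
               class = "tremorlock_error_validation")

  solA <- sol
  solA$Jmag <- sol$Jmag * 1.072
  expect_equal(montage_contrast(solA, sol, mask1), 7.2, tolerance = 1e-9)
  expect_equal(montage_contrast(sol, sol, mask1), 0)
  solB <- sol
  solB$Jmag <- sol$Jmag * 0
  expect_error(montage_contrast(sol, solB, mask1),
               class = "tremorlock_error_degenerate")
  tiny <- solve_laplace(plate_cube(n = 8), tol = 1e-8)
  expect_error(montage_contrast(sol, tiny, mask1),
               class = "tremorlock_error_validation")
})

test_that("discretisation error shrinks under grid refinement on a graded medium", {
  # conductivity graded linearly across the gap: phi(z) ~ log(1 + z / L),
  # a closed form the voxel scheme only approximates (the uniform plate is
  # reproduced exactly, so it cannot probe convergence)
  err_at <- function(h_mm) {
    span <- 32                    # plate-centre separation, mm
    nz <- round(span / h_mm) + 1L
    nxy <- 4L
    lab <- array(rep(seq_len(nz), each = nxy * nxy), dim = c(nxy, nxy, nz))
    z <- (seq_len(nz) - 1) * h_mm  # 0 at the bottom plate centre
    sig0 <- 0.2
    tis <- tibble::tibble(label = seq_len(nz),
                          tissue = sprintf("g%d", seq_len(nz)),
                          sigma = sig0 * (1 + z / span))
    m <- voxel_model(lab, h_mm, tis)
    hi <- array(FALSE, dim = dim(lab)); hi[, , nz] <- TRUE
    lo <- array(FALSE, dim = dim(lab)); lo[, , 1] <- TRUE
    m <- electrode_from_mask(m, hi, "source", 1)
    m <- electrode_from_mask(m, lo, "return", -1)
    sol <- solve_laplace(m, tol = 1e-12)
    phi_true <- -1 + 2 * log(1 + z / span) / log(2)
    max(abs(sol$phi[2, 2, ] - phi_true))
  }
  errs <- c(err_at(4), err_at(2), err_at(1))
  expect_true(all(diff(errs) < 0))
})
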