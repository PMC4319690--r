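# Quasi-static voxel current-density solver: finite-volume discretization of
# div(sigma grad phi) = 0 with harmonic-mean face conductivities, Dirichlet
# electrode voxels, and a Jacobi-preconditioned conjugate-gradient solve.

#' Reference isotropic tissue conductivities
#'
#' The standard table used throughout the solver, in S/m: skin 0.43, bone
#' 0.0064, gray matter 0.33, white matter 0.142, cerebrospinal fluid 1.79,
#' saline 0.367, air 1e-4, and 0.08 for remaining "average" soft tissue
#' (muscle/fat). Air is treated as a genuine (very poor) conductor so the
#' exterior needs no special casing.
#'
#' @return named numeric vector.
#' @export
tissue_conductivities <- function() {
  c(air = 1e-4, skin = 0.43, bone = 0.0064, gray = 0.33, white = 0.142,
    csf = 1.79, saline = 0.367, average = 0.08, electrode = 0.367)
}

#' Construct a voxel conductivity model
#'
#' @param labels 3-D integer array of tissue labels.
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @param tissues tibble with columns `label` (integer), `tissue` (name) and
#'   `sigma` (S/m > 0) covering every label present.
#' @return list of class `voxel_model` with `labels`, `voxel_size_mm`,
#'   `tissues`, `sigma` (3-D array of conductivities) and an empty
#'   `electrodes` list.
#' @export
voxel_model <- function(labels, voxel_size_mm, tissues) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  check_number(voxel_size_mm, "voxel_size_mm", lower = .Machine$double.eps)
  stopifnot(is.data.frame(tissues),
            all(c("label", "tissue", "sigma") %in% names(tissues)))
  if (any(!is.finite(tissues$sigma)) || any(tissues$sigma <= 0)) {
    stop_tremor("All conductivities must be > 0.", "validation")
  }
  present <- sort(unique(as.integer(labels)))
  if (!all(present %in% tissues$label)) {
    stop_tremor("Every label in the grid needs a conductivity.", "validation")
  }
  sigma_of <- setNames(tissues$sigma, tissues$label)
  sigma <- array(unname(sigma_of[as.character(labels)]), dim = dim(labels))
  structure(
    list(labels = labels, voxel_size_mm = voxel_size_mm,
         tissues = as_tibble(tissues), sigma = sigma, electrodes = list()),
    class = "voxel_model"
  )
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_model> %d x %d x %d voxels @ %g mm | tissues: %s | %d electrode(s)\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              paste(x$tissues$tissue, collapse = ", "), length(x$electrodes)))
  invisible(x)
}

#' Build a concentric-ellipsoid head phantom
#'
#' Voxelises nested ellipsoidal tissue layers (outermost first; by default
#' skin, skull bone, CSF, gray and white matter with plausible head
#' semi-axes), surrounded by at least one voxel of air on every face, with
#' an optional neck-and-shoulders block of average soft tissue fused below.
#' Conductivities come from [tissue_conductivities()] unless a layer
#' provides its own `sigma`.
#'
#' @param layers named list, outermost first; each element is either a
#'   length-3 numeric vector of ellipsoid semi-axes in mm, or a list with
#'   `semi_axes` and optional `sigma`. Layer names must be tissues from
#'   [tissue_conductivities()] when `sigma` is not given.
#' @param voxel_size_mm voxel edge, mm (2-4 mm is typical).
#' @param shoulders add the extracephalic block (average tissue, 0.08 S/m).
#' @param pad_voxels air padding on each face (>= 1).
#' @return a [voxel_model()].
#' @examples
#' ph <- build_phantom(voxel_size_mm = 8)
#' ph
#' @export
build_phantom <- function(layers = list(skin = c(75, 95, 70),
                                        bone = c(69, 89, 64),
                                        csf = c(62, 82, 57),
                                        gray = c(59, 79, 54),
                                        white = c(55, 75, 50)),
                          voxel_size_mm = 2, shoulders = FALSE,
                          pad_voxels = 2L) {
  stopifnot(length(layers) >= 1L, pad_voxels >= 1L)
  std <- tissue_conductivities()
  semi <- map(layers, function(l) if (is.list(l)) l$semi_axes else l)
  sig <- imap(layers, function(l, nm) {
    s <- if (is.list(l)) l$sigma %||% std[[nm]] else std[[nm]]
    if (is.null(s) || is.na(s)) {
      stop_tremor(sprintf("No conductivity known for layer '%s'.", nm), "validation")
    }
    s
  })
  for (i in seq_along(semi)) {
    if (length(semi[[i]]) != 3L || any(semi[[i]] <= 0)) {
      stop_tremor("Each layer needs 3 positive semi-axes (mm).", "validation")
    }
    if (i > 1L && any(semi[[i]] >= semi[[i - 1L]])) {
      stop_tremor("Layers must be strictly nested (outer to inner).", "validation")
    }
  }
  h <- voxel_size_mm
  outer_semi <- semi[[1L]]
  half <- outer_semi + pad_voxels * h
  nvox <- 2L * ceiling(half / h)
  if (shoulders) nvox[3] <- nvox[3] + ceiling(60 / h)  # extend downward
  cx <- (seq_len(nvox[1]) - 0.5) * h - nvox[1] * h / 2
  cy <- (seq_len(nvox[2]) - 0.5) * h - nvox[2] * h / 2
  # head centred at z = 0; any shoulder extension occupies negative z
  cz <- (seq_len(nvox[3]) - 0.5) * h - (nvox[3] * h - (half[3] * 2)) - half[3]

  labels <- array(0L, dim = nvox)
  X <- array(cx, dim = nvox)
  Y <- array(rep(cy, each = nvox[1]), dim = nvox)
  Z <- array(rep(cz, each = nvox[1] * nvox[2]), dim = nvox)
  for (i in seq_along(semi)) {
    s <- semi[[i]]
    inside <- (X / s[1])^2 + (Y / s[2])^2 + (Z / s[3])^2 <= 1
    labels[inside] <- i
  }
  tissues <- tibble(label = c(0L, seq_along(layers)),
                    tissue = c("air", names(layers)),
                    sigma = c(std[["air"]], unlist(sig)))
  if (shoulders) {
    blk <- abs(X) <= outer_semi[1] * 1.6 & abs(Y) <= outer_semi[2] &
      Z < -outer_semi[3] * 0.55 & Z > cz[pad_voxels + 1L] &
      abs(X) >= 0  # solid block under the head
    blk <- blk & labels == 0L
    lbl_sh <- length(layers) + 1L
    labels[blk] <- lbl_sh
    tissues <- bind_rows(tissues,
                         tibble(label = lbl_sh, tissue = "average",
                                sigma = std[["average"]]))
  }
  voxel_model(labels, voxel_size_mm, tissues)
}

# locate label ids, adding the tissue to the table when absent
ensure_tissue <- function(model, tissue) {
  row <- model$tissues[model$tissues$tissue == tissue, ]
  if (nrow(row)) return(list(model = model, label = row$label[1]))
  lbl <- max(model$tissues$label) + 1L
  sg <- tissue_conductivities()[[tissue]]
  model$tissues <- bind_rows(model$tissues,
                             tibble(label = lbl, tissue = tissue, sigma = sg))
  list(model = model, label = lbl)
}

#' Attach a rectangular electrode pad
#'
#' Places a conductive-rubber pad (default 50 x 70 mm) on the phantom
#' surface: for every grid column under the pad footprint the outermost
#' non-air voxel is found along the pad's normal axis, a saline layer
#' (default 2 mm, 0.367 S/m) is inserted on top of the skin, and one voxel
#' layer above it becomes the Dirichlet electrode held at `potential` volts.
#'
#' @param model a [voxel_model()].
#' @param center_mm length-2 position of the pad centre in the two tangent
#'   axes (mm, grid coordinates centred on the volume).
#' @param size_mm pad extent in the two tangent axes, mm.
#' @param role `"source"` or `"return"`.
#' @param potential electrode potential, volts (+1 source / -1 return by
#'   convention).
#' @param normal one of `"+x" "-x" "+y" "-y" "+z" "-z"`: the outward axis the
#'   pad faces.
#' @param saline_thickness_mm thickness of the saline layer, mm.
#' @return the modified model, with the electrode appended to
#'   `model$electrodes` (each electrode holds its Dirichlet voxel indices,
#'   role and potential).
#' @export
attach_electrode <- function(model, center_mm = c(0, 0), size_mm = c(50, 70),
                             role = c("source", "return"), potential = NULL,
                             normal = "+z", saline_thickness_mm = 2) {
  stopifnot(inherits(model, "voxel_model"))
  role <- match.arg(role)
  potential <- potential %||% if (role == "source") 1 else -1
  axes <- c("x" = 1L, "y" = 2L, "z" = 3L)
  dir_sign <- if (substr(normal, 1, 1) == "-") -1L else 1L
  ax <- axes[[substr(normal, 2, 2)]]
  tang <- setdiff(1:3, ax)
  dims <- dim(model$labels)
  h <- model$voxel_size_mm
  centers <- lapply(dims, function(nn) (seq_len(nn) - 0.5) * h - nn * h / 2)

  sel_u <- which(abs(centers[[tang[1]]] - center_mm[1]) <= size_mm[1] / 2)
  sel_v <- which(abs(centers[[tang[2]]] - center_mm[2]) <= size_mm[2] / 2)
  if (!length(sel_u) || !length(sel_v)) {
    stop_tremor("Pad footprint lies outside the grid.", "validation")
  }
  res <- ensure_tissue(model, "saline")
  model <- res$model; lbl_sal <- res$label
  res <- ensure_tissue(model, "electrode")
  model <- res$model; lbl_el <- res$label

  air_lbl <- model$tissues$label[model$tissues$tissue == "air"]
  is_air <- array(model$labels %in% air_lbl, dim = dims)
  existing <- unlist(lapply(model$electrodes, `[[`, "voxels"))
  n_sal <- max(1L, round(saline_thickness_mm / h))
  scan <- if (dir_sign > 0) rev(seq_len(dims[ax])) else seq_len(dims[ax])

  elec_vox <- integer(0)
  sal_vox <- integer(0)
  hit_center <- FALSE
  cu <- centers[[tang[1]]]; cv <- centers[[tang[2]]]
  for (iu in sel_u) for (iv in sel_v) {
    idx3 <- integer(3)
    idx3[tang[1]] <- iu; idx3[tang[2]] <- iv
    surf <- NA_integer_
    for (ia in scan) {
      idx3[ax] <- ia
      li <- lin_index(idx3[1], idx3[2], idx3[3], dims)
      if (!is_air[li]) { surf <- ia; break }
    }
    if (is.na(surf)) next
    if (abs(cu[iu] - center_mm[1]) <= h && abs(cv[iv] - center_mm[2]) <= h) {
      hit_center <- TRUE
    }
    outward <- surf + dir_sign * seq_len(n_sal + 1L)
    if (any(outward < 1L | outward > dims[ax])) {
      stop_tremor("Pad would extend past the grid; add air padding.", "validation")
    }
    idx3[ax] <- outward[n_sal + 1L]
    ev <- lin_index(idx3[1], idx3[2], idx3[3], dims)
    sv <- vapply(outward[seq_len(n_sal)], function(ia) {
      idx3[ax] <- ia
      lin_index(idx3[1], idx3[2], idx3[3], dims)
    }, integer(1))
    elec_vox <- c(elec_vox, ev)
    sal_vox <- c(sal_vox, sv)
  }
  if (!length(elec_vox) || !hit_center) {
    stop_tremor("Pad centre is not over the phantom surface.", "validation")
  }
  if (length(intersect(elec_vox, existing)) ||
      length(intersect(sal_vox, existing))) {
    stop_tremor("Pad overlaps an existing electrode.", "validation")
  }
  model$labels[sal_vox] <- lbl_sal
  model$labels[elec_vox] <- lbl_el
  sigma_of <- setNames(model$tissues$sigma, model$tissues$label)
  model$sigma <- array(unname(sigma_of[as.character(model$labels)]), dim = dims)
  model$electrodes <- c(model$electrodes,
                        list(list(voxels = elec_vox, role = role,
                                  potential = potential,
                                  saline_voxels = sal_vox)))
  model
}

#' Define an electrode directly from a voxel mask
#'
#' Lower-level alternative to [attach_electrode()] for idealised geometries
#' (full faces of a slab, point-like pads): marks the given voxels as
#' Dirichlet nodes at a fixed potential without inserting saline.
#'
#' @param model a [voxel_model()].
#' @param mask logical array (same dims) or integer voxel indices.
#' @param role `"source"` or `"return"`.
#' @param potential volts.
#' @return the modified model.
#' @export
electrode_from_mask <- function(model, mask, role = c("source", "return"),
                                potential = NULL) {
  stopifnot(inherits(model, "voxel_model"))
  role <- match.arg(role)
  potential <- potential %||% if (role == "source") 1 else -1
  vox <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(vox)) stop_tremor("Empty electrode mask.", "validation")
  existing <- unlist(lapply(model$electrodes, `[[`, "voxels"))
  if (length(intersect(vox, existing))) {
    stop_tremor("Electrode overlaps an existing electrode.", "validation")
  }
  model$electrodes <- c(model$electrodes,
                        list(list(voxels = vox, role = role,
                                  potential = potential, saline_voxels = integer(0))))
  model
}

# face conductances between voxel pairs along one axis (S); harmonic mean of
# the two voxel conductivities times the voxel edge (face area / distance = h)
face_conductance <- function(s1, s2, h_m) {
  2 * s1 * s2 / (s1 + s2) * h_m
}

# neighbour index offsets for the 3 axes
axis_pairs <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- array(seq_len(nx * ny * nz), dim = dims)
  list(
    list(a = as.vector(idx[-nx, , ]), b = as.vector(idx[-1, , ])),
    list(a = as.vector(idx[, -ny, ]), b = as.vector(idx[, -1, ])),
    list(a = as.vector(idx[, , -nz]), b = as.vector(idx[, , -1]))
  )
}

#' Solve the quasi-static Laplace problem on a voxel model
#'
#' Finite-volume discretization of `div(sigma grad phi) = 0` with
#' harmonic-mean face conductivities and zero-flux outer boundaries; the
#' electrode voxels are Dirichlet nodes held exactly at their potentials.
#' The symmetric positive-definite system is solved by Jacobi-preconditioned
#' conjugate gradients (deterministic zero initialisation) to relative
#' residual `tol`. The electric field follows by central differences
#' (`E = -grad phi`), the current density as `J = sigma E`, and the injected
#' current as the net conductance-weighted flux out of the source pad.
#'
#' @param model a [voxel_model()] with exactly one source and one return
#'   electrode (see [attach_electrode()] / [electrode_from_mask()]).
#' @param electrodes electrode list; defaults to `model$electrodes`.
#' @param tol relative residual tolerance (default 1e-9).
#' @param max_iter conjugate-gradient iteration cap.
#' @return list of class `field_solution`: `phi` (V), `E` (list of 3 arrays,
#'   V/m), `J` (A/m^2), `Jmag`, `injected_current` (A), `model`,
#'   `iterations`, `residual`.
#' @export
solve_laplace <- function(model, electrodes = model$electrodes,
                          tol = 1e-9, max_iter = 20000L) {
  stopifnot(inherits(model, "voxel_model"))
  roles <- vapply(electrodes, `[[`, character(1), "role")
  if (sum(roles == "source") != 1L || sum(roles == "return") != 1L) {
    stop_tremor("Need exactly one source and one return electrode.", "validation")
  }
  dims <- dim(model$labels)
  N <- prod(dims)
  h_m <- model$voxel_size_mm / 1000
  sig <- as.vector(model$sigma)

  phi_fixed <- rep(NA_real_, N)
  for (el in electrodes) phi_fixed[el$voxels] <- el$potential
  dirichlet <- !is.na(phi_fixed)
  unknown <- which(!dirichlet)
  red <- integer(N)
  red[unknown] <- seq_along(unknown)

  pairs <- axis_pairs(dims)
  ia <- unlist(lapply(pairs, `[[`, "a"), use.names = FALSE)
  ib <- unlist(lapply(pairs, `[[`, "b"), use.names = FALSE)
  g <- face_conductance(sig[ia], sig[ib], h_m)

  a_unk <- !dirichlet[ia]
  b_unk <- !dirichlet[ib]
  both <- a_unk & b_unk
  mixed_a <- a_unk & !b_unk   # a unknown, b Dirichlet
  mixed_b <- !a_unk & b_unk

  nu <- length(unknown)
  diag_acc <- numeric(nu)
  add_diag <- function(acc, idx, val) {
    tab <- rowsum(val, idx)
    acc[as.integer(rownames(tab))] <- acc[as.integer(rownames(tab))] + tab[, 1]
    acc
  }
  diag_acc <- add_diag(diag_acc, red[ia[a_unk]], g[a_unk])
  diag_acc <- add_diag(diag_acc, red[ib[b_unk]], g[b_unk])

  b_vec <- numeric(nu)
  if (any(mixed_a)) {
    b_vec <- add_diag(b_vec, red[ia[mixed_a]], g[mixed_a] * phi_fixed[ib[mixed_a]])
  }
  if (any(mixed_b)) {
    b_vec <- add_diag(b_vec, red[ib[mixed_b]], g[mixed_b] * phi_fixed[ia[mixed_b]])
  }

  A <- Matrix::sparseMatrix(
    i = c(seq_len(nu), red[ia[both]], red[ib[both]]),
    j = c(seq_len(nu), red[ib[both]], red[ia[both]]),
    x = c(diag_acc, -g[both], -g[both]),
    dims = c(nu, nu)
  )

  # Jacobi-preconditioned CG, zero start
  x <- numeric(nu)
  r <- b_vec
  Minv <- 1 / diag_acc
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b_vec^2))
  if (bnorm == 0) bnorm <- 1
  iter <- 0L
  repeat {
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) break
    if (iter >= max_iter) {
      stop_tremor(sprintf("CG did not converge in %d iterations (residual %.3e).",
                          max_iter, res), "solver")
    }
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    iter <- iter + 1L
  }

  phi <- phi_fixed
  phi[unknown] <- x
  phi_arr <- array(phi, dim = dims)

  E <- lapply(1:3, function(ax) -central_diff(phi_arr, ax, h_m))
  J <- lapply(E, function(e) model$sigma * e)
  Jmag <- sqrt(J[[1]]^2 + J[[2]]^2 + J[[3]]^2)

  src <- electrodes[[which(roles == "source")]]
  injected <- voxel_set_outflux(phi, src$voxels, ia, ib, g)

  structure(
    list(phi = phi_arr, E = E, J = J, Jmag = Jmag,
         injected_current = injected, model = model,
         iterations = iter, residual = res,
         faces = list(ia = ia, ib = ib, g = g)),
    class = "field_solution"
  )
}

# net conductance flux out of a voxel set (A)
voxel_set_outflux <- function(phi, voxels, ia, ib, g) {
  inset <- logical(length(phi))
  inset[voxels] <- TRUE
  out_a <- inset[ia] & !inset[ib]
  out_b <- inset[ib] & !inset[ia]
  sum(g[out_a] * (phi[ia[out_a]] - phi[ib[out_a]])) +
    sum(g[out_b] * (phi[ib[out_b]] - phi[ia[out_b]]))
}

#' Net current through the surface of a voxel set
#'
#' Discrete conductance-weighted flux out of an arbitrary voxel set — the
#' operator used both for the injected current and for checking discrete
#' current conservation (the flux through any closed surface containing
#' neither electrode should vanish to solver tolerance).
#'
#' @param sol a [solve_laplace()] solution.
#' @param mask logical array or voxel indices defining the enclosed set.
#' @return signed current, amperes.
#' @export
current_through <- function(sol, mask) {
  stopifnot(inherits(sol, "field_solution"))
  vox <- if (is.logical(mask)) which(mask) else as.integer(mask)
  voxel_set_outflux(as.vector(sol$phi), vox,
                    sol$faces$ia, sol$faces$ib, sol$faces$g)
}

# central differences along one axis, one-sided at the grid boundary
central_diff <- function(arr, axis, h_m) {
  dims <- dim(arr)
  n <- dims[axis]
  sl <- function(ix) {
    idx <- lapply(dims, seq_len)
    idx[[axis]] <- ix
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  spacing <- c(1, rep(2, n - 2L), 1) * h_m
  w <- array(1 / spacing[slice_rep_index(dims, axis)], dim = dims)
  (sl(c(2:n, n)) - sl(c(1, 1:(n - 1)))) * w
}

# index pattern replicating a per-axis weight vector over the full array
slice_rep_index <- function(dims, axis) {
  if (axis == 1L) rep(seq_len(dims[1]), times = dims[2] * dims[3])
  else if (axis == 2L) rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  else rep(seq_len(dims[3]), each = dims[1] * dims[2])
}

#' Rescale a field solution to a target injected current
#'
#' The problem is linear, so potentials and fields scale together; the paper
#' convention rescales the +/-1 V solution to a 1 mA source.
#'
#' @param sol a [solve_laplace()] solution with positive injected current.
#' @param target target current, amperes (default 1 mA).
#' @return rescaled `field_solution` with `injected_current == target`.
#' @export
scale_to_current <- function(sol, target = 1e-3) {
  stopifnot(inherits(sol, "field_solution"))
  if (!is.finite(sol$injected_current) || sol$injected_current <= 0) {
    stop_tremor("Injected current must be > 0 to rescale.", "degenerate")
  }
  k <- target / sol$injected_current
  sol$phi <- sol$phi * k
  sol$E <- lapply(sol$E, `*`, k)
  sol$J <- lapply(sol$J, `*`, k)
  sol$Jmag <- sol$Jmag * k
  sol$injected_current <- target
  sol
}

#' Mean current-density magnitude over a region of interest
#'
#' @param sol a `field_solution`.
#' @param mask logical array (same dims as the grid) or voxel indices.
#' @return mean `|J|` over the mask, A/m^2.
#' @export
roi_mean_density <- function(sol, mask) {
  stopifnot(inherits(sol, "field_solution"))
  vox <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(vox)) stop_tremor("Empty ROI mask.", "validation")
  mean(sol$Jmag[vox])
}

#' Relative current-density contrast between two montages
#'
#' `100 * (roi_mean(A) - roi_mean(B)) / roi_mean(B)` over a shared ROI — the
#' comparison form used to contrast return-electrode montages.
#'
#' @param sol_a,sol_b `field_solution`s on the same grid.
#' @param mask ROI (logical array or indices).
#' @return percent difference.
#' @export
montage_contrast <- function(sol_a, sol_b, mask) {
  if (!identical(dim(sol_a$phi), dim(sol_b$phi))) {
    stop_tremor("Solutions must share the same grid.", "validation")
  }
  b <- roi_mean_density(sol_b, mask)
  if (b == 0) stop_tremor("Reference ROI mean is zero.", "degenerate")
  100 * (roi_mean_density(sol_a, mask) - b) / b
}

#' Spherical region-of-interest mask
#'
#' @param model a [voxel_model()].
#' @param center_mm sphere centre in grid coordinates (mm, volume-centred).
#' @param radius_mm sphere radius, mm.
#' @return logical array over the grid.
#' @export
roi_sphere <- function(model, center_mm, radius_mm) {
  dims <- dim(model$labels)
  h <- model$voxel_size_mm
  cx <- (seq_len(dims[1]) - 0.5) * h - dims[1] * h / 2
  cy <- (seq_len(dims[2]) - 0.5) * h - dims[2] * h / 2
  cz <- (seq_len(dims[3]) - 0.5) * h - dims[3] * h / 2
  X <- array(cx, dims)
  Y <- array(rep(cy, each = dims[1]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  (X - center_mm[1])^2 + (Y - center_mm[2])^2 + (Z - center_mm[3])^2 <= radius_mm^2
}

#' Export potential and current-density volumes as NIfTI
#'
#' Writes `phi` and `Jmag` as NIfTI volumes with the voxel size in the
#' header. Requires the RNifti package.
#'
#' @param sol a `field_solution`.
#' @param prefix output path prefix; `<prefix>_phi.nii.gz` and
#'   `<prefix>_jmag.nii.gz` are written.
#' @return the written paths, invisibly.
#' @export
write_field_nifti <- function(sol, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_tremor("RNifti is required for NIfTI export.", "io")
  }
  h <- sol$model$voxel_size_mm
  paths <- c(paste0(prefix, "_phi.nii.gz"), paste0(prefix, "_jmag.nii.gz"))
  img1 <- RNifti::asNifti(sol$phi, pixdim = c(h, h, h))
  img2 <- RNifti::asNifti(sol$Jmag, pixdim = c(h, h, h))
  RNifti::writeNifti(img1, paths[1])
  RNifti::writeNifti(img2, paths[2])
  invisible(paths)
}
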