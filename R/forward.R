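#' Pixelated sensor grid on the diamond plane
#'
#' Square field of view centred on the origin of the diamond surface
#' (`z = plane_z`, default 0), divided into `pixels x pixels` square pixels.
#' Each pixel reading is the mean of the field over a
#' `subsamples x subsamples` sub-grid covering the pixel, emulating the
#' spatial averaging of the fluorescence readout; `subsamples = 1` is
#' pixel-centre point sampling.
#'
#' @param extent_um Side length of the field of view, µm.
#' @param pixels Number of pixels per side.
#' @param plane_z Height of the sensing plane, µm.
#' @param subsamples Sub-sampling points per pixel side (>= 1).
#' @return A list of class `ms_grid` with the pixel size `delta_um`, the
#'   field-of-view area `a_fov_um2` and the sample-point coordinates.
#' @export
sensor_grid <- function(extent_um = 1000, pixels = 20, plane_z = 0,
                        subsamples = 4) {
  check_positive(extent_um, "extent_um")
  if (pixels < 1 || pixels != round(pixels)) abort("`pixels` must be a positive integer")
  if (subsamples < 1 || subsamples != round(subsamples)) {
    abort("`subsamples` must be a positive integer")
  }
  delta <- extent_um / pixels
  centers <- -extent_um / 2 + (seq_len(pixels) - 0.5) * delta
  off <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * delta
  sx <- as.vector(outer(centers, off, "+"))
  pts <- expand.grid(x = sx, y = sx)
  structure(list(
    extent_um = extent_um, pixels = as.integer(pixels),
    delta_um = delta, a_fov_um2 = extent_um^2,
    plane_z = plane_z, subsamples = as.integer(subsamples),
    centers = centers,
    points = cbind(x = pts$x, y = pts$y, z = plane_z)
  ), class = "ms_grid")
}

# average sub-sampled point values (rows = length(centers)*subsamples per
# axis, expanded by expand.grid) down to a pixels x pixels matrix
pixel_average <- function(values, grid) {
  M <- grid$pixels
  s <- grid$subsamples
  a <- array(values, dim = c(M, s, M, s))
  apply(a, c(1, 3), mean)
}

segments_matrix <- function(compartments) {
  as.matrix(compartments[, c("x0", "y0", "z0", "x1", "y1", "z1")])
}

#' Magnetic field of finite line-current segments
#'
#' Exact finite-segment Biot-Savart field of a set of straight compartments
#' carrying axial currents, superposed at arbitrary field points. For each
#' segment the field is
#' `B = (mu0/4pi) (I t x rho_hat / rho) [l/sqrt(l^2+rho^2) - h/sqrt(h^2+rho^2)]`
#' where `t` is the segment direction, `rho` the perpendicular distance of
#' the field point from the segment axis, `l` the longitudinal distance from
#' the segment start to the foot of the perpendicular and `h = l - length`
#' the distance from the segment end. In µm/nA units `mu0/4pi = 0.1` nT·µm/nA.
#'
#' @param compartments Data frame or matrix with columns
#'   `x0,y0,z0,x1,y1,z1` (µm), one row per segment.
#' @param currents Axial currents, nA: a vector (one per segment) or a
#'   segments x q matrix to evaluate `q` current patterns that share the
#'   geometry in a single pass.
#' @param points Field points, an n x 3 matrix (µm).
#' @param eps_geom Points closer than this to any segment axis raise an
#'   error naming the offending segment, µm.
#' @param chunk_size Maximum number of point-segment pairs evaluated at
#'   once (memory control).
#' @return For vector `currents` an n x 3 matrix of B (nT, columns
#'   `Bx,By,Bz`); for matrix currents an n x 3 x q array.
#' @export
bfield_line_sources <- function(compartments, currents, points,
                                eps_geom = ms_constants$eps_geom,
                                chunk_size = 2e6) {
  line_source_sum(compartments, currents, points, eps_geom, chunk_size,
                  kernel = "bfield")
}

#' Extracellular potential of line membrane-current sources
#'
#' Line-source approximation of the local field potential in an infinite
#' homogeneous volume conductor: each compartment spreads its transmembrane
#' current uniformly along its axis, giving
#' `phi = (1/4pi sigma) (Im/len) log|(sqrt(h^2+rho^2)-h)/(sqrt(l^2+rho^2)-l)|`
#' summed over compartments. With nA, µm and S/m the result is in mV.
#'
#' @inheritParams bfield_line_sources
#' @param Im Transmembrane currents, nA (vector or segments x q matrix).
#' @param sigma_cond Extracellular conductivity, S/m.
#' @return n-vector (or n x q matrix) of potentials, mV.
#' @export
lfp_line_sources <- function(compartments, Im, points, sigma_cond = 0.3,
                             eps_geom = ms_constants$eps_geom,
                             chunk_size = 2e6) {
  check_positive(sigma_cond, "sigma_cond")
  line_source_sum(compartments, Im, points, eps_geom, chunk_size,
                  kernel = "lfp", sigma_cond = sigma_cond)
}

# shared chunked evaluation of the two line-source kernels
line_source_sum <- function(compartments, currents, points, eps_geom,
                            chunk_size, kernel, sigma_cond = NULL) {
  seg <- if (is.matrix(compartments)) compartments else segments_matrix(compartments)
  currents <- as.matrix(currents)
  if (nrow(currents) != nrow(seg)) {
    abort("`currents` must have one row per segment")
  }
  points <- matrix(as.numeric(points), ncol = 3)
  S <- nrow(seg)
  P <- nrow(points)
  q <- ncol(currents)

  dx <- seg[, 4] - seg[, 1]
  dy <- seg[, 5] - seg[, 2]
  dz <- seg[, 6] - seg[, 3]
  ds <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(ds <= 0)) abort("zero-length segment")
  tx <- dx / ds
  ty <- dy / ds
  tz <- dz / ds

  if (kernel == "bfield") {
    out <- array(0, dim = c(P, 3, q))
  } else {
    out <- matrix(0, P, q)
  }
  pts_per_chunk <- max(1L, floor(chunk_size / S))
  for (p0 in seq(1, P, by = pts_per_chunk)) {
    p1 <- min(P, p0 + pts_per_chunk - 1)
    idx <- p0:p1
    wX <- outer(points[idx, 1], seg[, 1], "-") # (p x S)
    wY <- outer(points[idx, 2], seg[, 2], "-")
    wZ <- outer(points[idx, 3], seg[, 3], "-")
    l <- sweep(wX, 2, tx, "*") + sweep(wY, 2, ty, "*") + sweep(wZ, 2, tz, "*")
    h <- sweep(l, 2, ds, "-")
    rX <- wX - sweep(l, 2, tx, "*")
    rY <- wY - sweep(l, 2, ty, "*")
    rZ <- wZ - sweep(l, 2, tz, "*")
    rho <- sqrt(rX^2 + rY^2 + rZ^2)
    if (any(rho < eps_geom)) {
      bad <- which(rho < eps_geom, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "field point %d lies within %g um of the axis of segment %d",
        idx[bad[1]], eps_geom, bad[2]
      ))
    }
    sl <- sqrt(l^2 + rho^2)
    sh <- sqrt(h^2 + rho^2)
    if (kernel == "bfield") {
      fac <- ms_constants$mu0_4pi * (l / sl - h / sh) / rho^2
      # direction t x rho (rho un-normalised; absorbed via 1/rho^2 above)
      cx <- sweep(rZ, 2, ty, "*") - sweep(rY, 2, tz, "*")
      cy <- sweep(rX, 2, tz, "*") - sweep(rZ, 2, tx, "*")
      cz <- sweep(rY, 2, tx, "*") - sweep(rX, 2, ty, "*")
      for (j in seq_len(q)) {
        Ij <- currents[, j]
        out[idx, 1, j] <- out[idx, 1, j] + (fac * cx) %*% Ij
        out[idx, 2, j] <- out[idx, 2, j] + (fac * cy) %*% Ij
        out[idx, 3, j] <- out[idx, 3, j] + (fac * cz) %*% Ij
      }
    } else {
      kern <- log((sh - h) / (sl - l)) / (4 * pi * sigma_cond)
      kern <- sweep(kern, 2, ds, "/")
      out[idx, ] <- out[idx, ] + kern %*% currents
    }
  }
  if (kernel == "bfield") {
    dimnames(out)[[2]] <- c("Bx", "By", "Bz")
    if (q == 1) out <- out[, , 1, drop = TRUE]
    if (is.null(dim(out))) out <- matrix(out, ncol = 3,
                                         dimnames = list(NULL, c("Bx", "By", "Bz")))
  } else if (q == 1) {
    out <- drop(out)
  }
  out
}

#' Empirical volume-conductor correction for the tangential field
#'
#' The finite extracellular volume conductor attenuates the tangential
#' (`B_X`) field component; the effect is captured by a depth-dependent
#' scale factor `s(depth) = a1 + a2/(depth + c)` fitted externally (e.g. to
#' finite-element simulations). The identity correction `a1 = 1, a2 = 0` is
#' the default; fitted coefficients can be supplied. The normal component
#' `B_Z` and the electric potential are not corrected.
#'
#' @param a1 Dimensionless offset.
#' @param a2 Numerator of the rational part, µm.
#' @param c_um Depth offset of the rational part, µm.
#' @return A list of class `ms_correction`.
#' @export
volume_correction <- function(a1 = 1, a2 = 0, c_um = 0) {
  structure(list(a1 = a1, a2 = a2, c_um = c_um), class = "ms_correction")
}

correction_factor <- function(correction, depth) {
  correction$a1 + if (correction$a2 != 0) {
    correction$a2 / (depth + correction$c_um)
  } else {
    0
  }
}

#' Apply the volume-conductor scaling to a B_X map
#'
#' @param bx A `B_X` value, map or array, nT.
#' @param correction A [volume_correction()].
#' @param depth Effective source depth at which the correction is
#'   evaluated, µm (>= 0).
#' @return `bx` multiplied by `s(depth)`.
#' @export
apply_bx_correction <- function(bx, correction, depth) {
  check_positive(depth, "depth", allow_zero = TRUE)
  s <- correction_factor(correction, depth)
  if (s <= 0) abort(sprintf("correction factor s(%g) = %g is not positive", depth, s))
  bx * s
}

# -- population field rendering ----------------------------------------------

# Raw per-pair line-source kernels for a segment block: matrices p x S whose
# entries are the field at point i per unit current in segment j.
line_source_kernels <- function(seg, points, sigma_cond,
                                eps_geom = ms_constants$eps_geom) {
  dx <- seg[, 4] - seg[, 1]
  dy <- seg[, 5] - seg[, 2]
  dz <- seg[, 6] - seg[, 3]
  ds <- sqrt(dx^2 + dy^2 + dz^2)
  tx <- dx / ds
  ty <- dy / ds
  tz <- dz / ds
  wX <- outer(points[, 1], seg[, 1], "-")
  wY <- outer(points[, 2], seg[, 2], "-")
  wZ <- outer(points[, 3], seg[, 3], "-")
  l <- sweep(wX, 2, tx, "*") + sweep(wY, 2, ty, "*") + sweep(wZ, 2, tz, "*")
  h <- sweep(l, 2, ds, "-")
  rX <- wX - sweep(l, 2, tx, "*")
  rY <- wY - sweep(l, 2, ty, "*")
  rZ <- wZ - sweep(l, 2, tz, "*")
  rho <- sqrt(rX^2 + rY^2 + rZ^2)
  if (any(rho < eps_geom)) {
    bad <- which(rho < eps_geom, arr.ind = TRUE)[1, ]
    abort(sprintf("field point %d lies within %g um of the axis of segment %d",
                  bad[1], eps_geom, bad[2]))
  }
  sl <- sqrt(l^2 + rho^2)
  sh <- sqrt(h^2 + rho^2)
  fac <- ms_constants$mu0_4pi * (l / sl - h / sh) / rho^2
  phi <- sweep(log((sh - h) / (sl - l)), 2, ds, "/") / (4 * pi * sigma_cond)
  list(
    bx = fac * (sweep(rZ, 2, ty, "*") - sweep(rY, 2, tz, "*")),
    by = fac * (sweep(rX, 2, tz, "*") - sweep(rZ, 2, tx, "*")),
    bz = fac * (sweep(rY, 2, tx, "*") - sweep(rX, 2, ty, "*")),
    phi = phi
  )
}

# Per-cell separable decomposition: every compartment current is a fixed
# spatial profile times one of two shared temporal kernels (EPSP, AP), so the
# field at any point factorises into per-cell geometric couplings times
# per-cell kernel activation time courses. Computing the couplings costs one
# pass over all (point, segment) pairs; after that, full time-resolved maps
# are matrix products.
population_couplings <- function(population, params, region_weights, points,
                                 sigma_cond = 0.3, chunk_size = 4e6) {
  template <- attr(population, "template")
  aE <- axial_profile(template, profile_epsp(template, params, region_weights)) *
    params$epsp_amplitude * params$strength_scale
  aA <- axial_profile(template, profile_ap(template, params)) *
    params$ap_amplitude * params$strength_scale
  mE <- profile_epsp_current(template, params, region_weights) * params$strength_scale
  mA <- profile_ap_current(template, params) * params$strength_scale
  profB <- cbind(aE, aA)
  profI <- cbind(mE, mA)

  n_comp <- nrow(template)
  n_cells <- nrow(attr(population, "cells"))
  seg <- segments_matrix(population)
  P <- nrow(points)
  GXE <- GXA <- GZE <- GZA <- GYE <- GYA <- matrix(0, P, n_cells)
  PHE <- PHA <- matrix(0, P, n_cells)
  block <- max(1L, floor(chunk_size / max(P * n_comp, 1)))
  contract <- function(kern, nb, prof) {
    # kern: P x (n_comp*nb), compartment index fastest -> (P*nb) x n_comp
    a <- aperm(array(kern, dim = c(P, n_comp, nb)), c(1, 3, 2))
    array(matrix(a, P * nb, n_comp) %*% prof, dim = c(P, nb, 2))
  }
  for (c0 in seq(1, n_cells, by = block)) {
    c1 <- min(n_cells, c0 + block - 1)
    nb <- c1 - c0 + 1
    rows <- ((c0 - 1) * n_comp + 1):(c1 * n_comp)
    kk <- line_source_kernels(seg[rows, , drop = FALSE], points, sigma_cond)
    g <- contract(kk$bx, nb, profB)
    GXE[, c0:c1] <- g[, , 1]
    GXA[, c0:c1] <- g[, , 2]
    g <- contract(kk$by, nb, profB)
    GYE[, c0:c1] <- g[, , 1]
    GYA[, c0:c1] <- g[, , 2]
    g <- contract(kk$bz, nb, profB)
    GZE[, c0:c1] <- g[, , 1]
    GZA[, c0:c1] <- g[, , 2]
    g <- contract(kk$phi, nb, profI)
    PHE[, c0:c1] <- g[, , 1]
    PHA[, c0:c1] <- g[, , 2]
  }
  list(GXE = GXE, GXA = GXA, GYE = GYE, GYA = GYA, GZE = GZE, GZA = GZA,
       PHE = PHE, PHA = PHA)
}

# kernel activations per cell over a time base: the EPSP kernel, the AP
# depolarisation kernel (drives axial currents) and the biphasic AP
# membrane-current kernel (drives the extracellular potential)
schedule_activations <- function(schedule, params, times) {
  n_cells <- max(schedule$cell_id)
  sE <- matrix(0, n_cells, length(times))
  sA <- matrix(0, n_cells, length(times))
  sAI <- matrix(0, n_cells, length(times))
  spiking <- params$case == "spiking"
  for (i in seq_len(nrow(schedule))) {
    cid <- schedule$cell_id[i]
    te <- schedule$time_ms[i]
    sE[cid, ] <- sE[cid, ] + kernel_epsp(times - te, params$epsp_tau_rise,
                                         params$epsp_tau_decay)
    if (spiking) {
      sA[cid, ] <- sA[cid, ] + kernel_ap(times - te - params$ap_latency,
                                         params$ap_width)
      sAI[cid, ] <- sAI[cid, ] + kernel_ap_current(times - te - params$ap_latency,
                                                   params$ap_width)
    }
  }
  list(sE = sE, sA = sA, sAI = sAI)
}

#' Render time-resolved field maps of a population on the sensor grid
#'
#' Superposes the line-source magnetic field and extracellular potential of
#' every cell of the population on the pixelated sensor grid, for the
#' requested time frames. Two equivalent paths are provided: `"kernel"`
#' factorises the computation into per-cell geometric couplings times shared
#' temporal kernels (fast; the default), `"direct"` renders each frame by
#' explicit per-frame superposition of instantaneous compartment currents
#' (the reference path; used to validate the factorised one).
#'
#' @param population An `ms_population`.
#' @param schedule An `ms_schedule`.
#' @param params Calibrated [waveform_params()].
#' @param grid An [sensor_grid()].
#' @param times Time frames to render, ms.
#' @param correction A [volume_correction()] applied to `B_X` at the
#'   effective depth `dead_layer_z0 + active_thickness_d/2`.
#' @param sigma_cond Extracellular conductivity, S/m.
#' @param method `"kernel"` or `"direct"`.
#' @return A list of class `ms_field_map` with arrays `BX`, `BY`, `BZ` (nT)
#'   and `phi` (mV) of dimension pixels x pixels x length(times), the grid,
#'   the time base, and provenance metadata.
#' @export
render_field_map <- function(population, schedule, params, grid,
                             times = seq(0, params$duration, by = 0.25),
                             correction = volume_correction(),
                             sigma_cond = 0.3,
                             method = c("kernel", "direct")) {
  method <- match.arg(method)
  if (any(c(population$z0, population$z1) <= grid$plane_z)) {
    abort("all compartments must lie strictly above the sensor plane")
  }
  rw <- attr(schedule, "region_weights") %||% c(apical = 0.5, basal = 0.5)
  M <- grid$pixels
  pts <- grid$points
  if (method == "kernel") {
    G <- population_couplings(population, params, rw, pts, sigma_cond)
    act <- schedule_activations(schedule, params, times)
    BX <- G$GXE %*% act$sE + G$GXA %*% act$sA
    BY <- G$GYE %*% act$sE + G$GYA %*% act$sA
    BZ <- G$GZE %*% act$sE + G$GZA %*% act$sA
    PH <- G$PHE %*% act$sE + G$PHA %*% act$sAI
  } else {
    template <- attr(population, "template")
    n_comp <- nrow(template)
    cells <- attr(population, "cells")
    ev <- split(schedule$time_ms, schedule$cell_id)
    BX <- BY <- BZ <- PH <- matrix(0, nrow(pts), length(times))
    seg <- segments_matrix(population)
    for (ti in seq_along(times)) {
      Ia <- numeric(nrow(seg))
      Im <- numeric(nrow(seg))
      for (ci in seq_len(nrow(cells))) {
        a <- generate_cell_activity(template, ev[[as.character(ci)]] %||% numeric(),
                                    params, region_weights = rw,
                                    times = times[ti])
        rows <- ((ci - 1) * n_comp + 1):(ci * n_comp)
        Ia[rows] <- a$I_axial[, 1]
        Im[rows] <- a$Im[, 1]
      }
      B <- bfield_line_sources(seg, Ia, pts)
      BX[, ti] <- B[, 1]
      BY[, ti] <- B[, 2]
      BZ[, ti] <- B[, 3]
      PH[, ti] <- lfp_line_sources(seg, Im, pts, sigma_cond)
    }
  }
  layout <- attr(population, "layout")
  depth <- layout$dead_layer_z0 + layout$active_thickness_d / 2
  s_corr <- correction_factor(correction, depth)
  to_maps <- function(flat, scale = 1) {
    out <- array(0, dim = c(M, M, length(times)))
    for (ti in seq_along(times)) {
      out[, , ti] <- pixel_average(flat[, ti], grid) * scale
    }
    out
  }
  structure(list(
    grid = grid, time_ms = times,
    BX = to_maps(BX, s_corr), BY = to_maps(BY), BZ = to_maps(BZ),
    phi = to_maps(PH),
    sigma_cond = sigma_cond, correction = correction,
    meta = list(
      n_cells = nrow(attr(population, "cells")),
      seed = attr(population, "seed"),
      schedule_seed = attr(schedule, "seed"),
      method = method
    )
  ), class = "ms_field_map")
}

#' @export
print.ms_field_map <- function(x, ...) {
  cat(sprintf(
    "<ms_field_map> %d x %d pixels (%.3g um), %d frames; peak |BX| = %.3g nT\n",
    x$grid$pixels, x$grid$pixels, x$grid$delta_um, length(x$time_ms),
    max(abs(x$BX))
  ))
  invisible(x)
}
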