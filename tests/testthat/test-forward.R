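test_that("finite-segment field reproduces the infinite-wire closed form", {
  seg <- cbind(0, -5e5, 0, 0, 5e5, 0) # 1e6 um wire along Y
  B <- bfield_line_sources(seg, 1, matrix(c(1, 0, 0), 1))
  # mu0 I / (2 pi rho) = 0.2 nT at rho = 1 um, I = 1 nA
  expect_equal(sqrt(sum(B^2)), 0.2, tolerance = 1e-6)
  expect_equal(unname(abs(B[1, "Bz"])), 0.2, tolerance = 1e-6)
  expect_equal(unname(B[1, "Bx"]), 0)
})

test_that("finite-segment field matches Biot-Savart quadrature", {
  seg <- c(3, -7, 2, 15, 4, 9)
  pts <- rbind(c(0, 0, 0), c(20, 5, -3), c(8, -2, 30), c(4, -6, 2.5))
  B <- bfield_line_sources(matrix(seg, 1), 2.5, pts)
  for (i in seq_len(nrow(pts))) {
    Bq <- bfield_quadrature(seg, 2.5, pts[i, ])
    expect_equal(unname(B[i, ]), Bq, tolerance = 1e-8)
  }
})

test_that("anti-parallel overlapping segments cancel and superpose linearly", {
  two <- rbind(c(0, -50, 0, 0, 50, 0), c(0, 50, 0, 0, -50, 0))
  B <- bfield_line_sources(two, c(1, 1), matrix(c(30, 10, 5), 1))
  expect_equal(max(abs(B)), 0)

  pts <- matrix(rnorm(15, sd = 100), 5)
  segs <- rbind(c(0, -50, 0, 0, 50, 0), c(20, 0, 10, 25, 30, 12))
  Bsum <- bfield_line_sources(segs, c(1.5, -2), pts)
  B1 <- bfield_line_sources(segs[1, , drop = FALSE], 1.5, pts)
  B2 <- bfield_line_sources(segs[2, , drop = FALSE], -2, pts)
  expect_equal(Bsum, B1 + B2)

  # multi-current interface agrees with separate calls
  Bm <- bfield_line_sources(segs, cbind(c(1.5, -2), c(1, 0)), pts)
  expect_equal(Bm[, , 1], Bsum)
  expect_equal(Bm[, , 2], bfield_line_sources(segs, c(1, 0), pts))
})

test_that("points on a segment axis raise an informative error", {
  seg <- matrix(c(0, -50, 0, 0, 50, 0), 1)
  expect_error(bfield_line_sources(seg, 1, matrix(c(1e-5, 0, 0), 1)),
               "segment 1")
  expect_error(lfp_line_sources(seg, 1, matrix(c(0, 60, 1e-5), 1)),
               "segment")
})

test_that("line-source potential has the right limits and scaling", {
  # short segment at large distance behaves as a point source I/(4 pi sigma r)
  ds <- 1
  seg <- matrix(c(0, -ds / 2, 0, 0, ds / 2, 0), 1)
  r <- 100 * ds
  phi <- lfp_line_sources(seg, 2, matrix(c(r, 0, 0), 1), sigma_cond = 0.3)
  expect_equal(phi, 2 / (4 * pi * 0.3 * r), tolerance = 1e-3)

  # linearity in the membrane current
  phi2 <- lfp_line_sources(seg, 4, matrix(c(r, 0, 0), 1), sigma_cond = 0.3)
  expect_equal(phi2, 2 * phi)

  # 1/sigma scaling
  phi3 <- lfp_line_sources(seg, 2, matrix(c(r, 0, 0), 1), sigma_cond = 0.6)
  expect_equal(phi3, phi / 2)

  # quadrature oracle at several points for a long oblique segment
  seg2 <- c(-20, -35, 5, 40, 25, 18)
  pts <- rbind(c(0, 0, -40), c(100, 3, 7), c(-9, 60, 22))
  phiv <- lfp_line_sources(matrix(seg2, 1), 1.7, pts, sigma_cond = 0.3)
  for (i in seq_len(nrow(pts))) {
    expect_equal(phiv[i], lfp_quadrature(seg2, 1.7, pts[i, ]),
                 tolerance = 1e-6)
  }
})

test_that("volume-conductor correction scales B_X as specified", {
  bx <- matrix(rnorm(16), 4)
  expect_equal(apply_bx_correction(bx, volume_correction(1, 0, 5), 30), bx)
  expect_equal(apply_bx_correction(bx, volume_correction(0.5, 0, 0), 30), bx / 2)
  expect_equal(apply_bx_correction(2, volume_correction(0.8, 20, 10), 30),
               2 * 1.3) # 0.8 + 20/40
  expect_error(apply_bx_correction(bx, volume_correction(-1, 0, 0), 10),
               "not positive")
})

test_that("field decays monotonically with standoff distance", {
  act <- generate_cell_activity(default_cell, 12.5, calibrated_params,
                                times = 14.5)
  seg <- as.matrix(default_cell[, c("x0", "y0", "z0", "x1", "y1", "z1")])
  z <- c(10, 20, 50, 100, 200, 400)
  peaks <- vapply(z, function(zi) {
    B <- bfield_line_sources(seg, act$I_axial[, 1],
                             matrix(c(0, 0, -zi), 1))
    sqrt(sum(B^2))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("field maps: pixel averaging, geometry signatures, superposition", {
  pop <- tiny_population(n_cells = 20, z0 = 50, seed = 31)
  sched <- sample_event_times(12.5, 0.5, 20, seed = 32)
  grid1 <- sensor_grid(400, 8, 0, 1)
  t_probe <- c(14, 15)
  fm <- render_field_map(pop, sched, calibrated_params, grid1, times = t_probe)

  # kernel and direct render paths agree to machine precision
  fmd <- render_field_map(pop, sched, calibrated_params, grid1,
                          times = t_probe, method = "direct")
  for (comp in c("BX", "BY", "BZ", "phi")) {
    expect_equal(fm[[comp]], fmd[[comp]], tolerance = 1e-12)
  }

  # B_Y is negligible for Y-oriented cells
  expect_lt(max(abs(fm$BY)), 0.05 * max(abs(fm$BX)))

  # uniform-field limit: a very distant source is unchanged by averaging
  grid_sub <- sensor_grid(400, 8, 0, 3)
  far <- tiny_population(n_cells = 3, z0 = 5e4, seed = 33)
  fm_far1 <- render_field_map(far, sample_event_times(12.5, 0, 3, seed = 1),
                              calibrated_params, grid1, times = 14.5)
  fm_far2 <- render_field_map(far, sample_event_times(12.5, 0, 3, seed = 1),
                              calibrated_params, grid_sub, times = 14.5)
  expect_equal(fm_far1$BX, fm_far2$BX, tolerance = 1e-4)

  # compartments at/below the sensor plane are rejected
  deep <- tiny_population(n_cells = 2, z0 = 50)
  deep$z0[1] <- -1
  expect_error(render_field_map(deep, sample_event_times(12.5, 0, 2, seed = 1),
                                calibrated_params, grid1, times = 14.5),
               "above the sensor plane")
})
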