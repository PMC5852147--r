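test_that("membrane currents are conserved and vanish without events", {
  quiet <- generate_cell_activity(default_cell, numeric(), calibrated_params)
  expect_true(all(quiet$Im == 0))
  expect_true(all(quiet$Vm == calibrated_params$v_rest))
  expect_true(all(quiet$I_axial == 0))

  for (p in list(calibrated_params, nonspiking_params)) {
    act <- generate_cell_activity(default_cell, c(12.5, 37.5), p)
    expect_lt(max(abs(colSums(act$Im))), 1e-9)
  }
  expect_error(generate_cell_activity(default_cell, 90, calibrated_params),
               "within")
})

test_that("axial currents are the parent finite difference", {
  # uniform potential: no axial current anywhere
  Vm <- matrix(-65, nrow(default_cell), 5)
  expect_true(all(compute_axial_currents(default_cell, Vm) == 0))

  # two compartments, 1 mV across 10 um at 0.1 MOhm/um -> 1 nA
  two <- tibble::tibble(
    compartment = 1:2, parent = c(NA, 1L), region = c("soma", "apical"),
    x0 = 0, y0 = c(0, 10), z0 = 0, x1 = 0, y1 = c(10, 20), z1 = 0,
    length_um = 10, r_axial = 0.1, arc_pos = c(5, 15)
  )
  Vm <- matrix(c(0, 0, 0, 1), 2, 2)
  Ia <- compute_axial_currents(two, Vm)
  expect_equal(Ia[2, 2], 1)
  expect_equal(Ia[1, ], c(0, 0)) # root convention

  # linear ramp along a uniform chain -> constant axial current
  chain <- build_template_cell(300, 200, 10, 0.5)
  apical <- chain[chain$region == "apical", ]
  Vm <- matrix(-65 + 0.01 * chain$arc_pos, ncol = 1)
  Ia <- compute_axial_currents(chain, Vm)
  in_chain <- which(chain$region == "apical" & chain$parent != 1)
  expect_lt(diff(range(Ia[in_chain, 1])), 1e-12)

  expect_error(compute_axial_currents(default_cell, Vm[1:3, , drop = FALSE]),
               "one row per compartment")
})

test_that("equivalent current dipole follows its defining sum", {
  one <- tibble::tibble(
    compartment = 1L, parent = NA_integer_, region = "soma",
    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 200, z1 = 0,
    length_um = 200, r_axial = 1, arc_pos = 100
  )
  q <- compute_ecd(one, matrix(1, 1, 1))
  expect_equal(unname(q$Q[1, ]), c(0, 0.2, 0)) # 1 nA x 200 um = 0.2 pA m

  # closed loop: equal and opposite currents on anti-parallel segments
  loop <- tibble::tibble(
    compartment = 1:2, parent = c(NA, 1L), region = c("soma", "apical"),
    x0 = c(0, 0), y0 = c(0, 200), z0 = 0,
    x1 = c(0, 0), y1 = c(200, 0), z1 = 0,
    length_um = 200, r_axial = 1, arc_pos = c(100, 100)
  )
  q <- compute_ecd(loop, matrix(c(1, 1), 2, 1))
  expect_equal(max(abs(q$Q)), 0)

  # linearity: N synchronized identical cells sum their dipoles
  act <- generate_cell_activity(default_cell, 12.5, calibrated_params)
  q1 <- compute_ecd(default_cell, act$I_axial)
  qN <- compute_ecd(default_cell, 7 * act$I_axial)
  expect_equal(qN$peak_magnitude, 7 * q1$peak_magnitude)

  # triangle inequality against the per-compartment bound
  bound <- colSums(abs(act$I_axial) * default_cell$length_um) / 1000
  expect_true(all(q1$magnitude <= bound + 1e-12))
})

test_that("dipole calibration is exact, linear and idempotent", {
  p <- calibrate_waveforms(waveform_params(), 0.2, default_cell)
  act <- generate_cell_activity(default_cell, 10, p)
  expect_equal(compute_ecd(default_cell, act$I_axial)$peak_magnitude, 0.2,
               tolerance = 1e-3)

  p4 <- calibrate_waveforms(waveform_params(), 0.4, default_cell)
  expect_equal(p4$ap_amplitude, 2 * p$ap_amplitude)
  expect_equal(p4$epsp_amplitude, 2 * p$epsp_amplitude)

  p_again <- calibrate_waveforms(p, 0.2, default_cell)
  expect_equal(p_again$ap_amplitude, p$ap_amplitude, tolerance = 1e-10)

  expect_error(calibrate_waveforms(waveform_params(), -1), "positive")
})

test_that("spiking traces carry more high-frequency power than EPSP-only", {
  spk <- generate_cell_activity(default_cell, 12.5, calibrated_params)
  eps <- generate_cell_activity(default_cell, 12.5, nonspiking_params)
  fs <- 1000 / calibrated_params$dt
  hf_power <- function(x) {
    sp <- cumulative_power(x, fs)
    1 - sp$cumulative_fraction[which(sp$frequency_hz >= 300)[1]]
  }
  soma_axial_spk <- colSums(abs(spk$I_axial))
  soma_axial_eps <- colSums(abs(eps$I_axial))
  expect_gt(hf_power(soma_axial_spk), hf_power(soma_axial_eps))
})

test_that("population dipole matches single-cell linearity under zero jitter", {
  pop <- tiny_population(n_cells = 200, z0 = 150)
  sched <- sample_event_times(12.5, 0, 200, seed = 21)
  pe <- population_ecd(pop, sched, calibrated_params)
  expect_equal(pe$peak_magnitude, 200 * 0.2, tolerance = 1e-6)
})
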