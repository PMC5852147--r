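# shared fixtures, built in code

default_cell <- build_template_cell()

calibrated_params <- calibrate_waveforms(waveform_params(), 0.2, default_cell)

nonspiking_params <- local({
  p <- calibrated_params
  p$case <- "non_spiking"
  p$strength_scale <- 0.5
  p
})

tiny_population <- function(n_cells = 5, z0 = 50, seed = 7) {
  layout <- population_layout(100, 100, 50, z0, n_cells, 50, 50)
  place_population(layout, default_cell, seed = seed)
}

# numerical quadrature of the Biot-Savart integral along one segment
# (independent oracle for the closed-form finite-segment field)
bfield_quadrature <- function(seg, current, point, n_nodes = 1000) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  a <- seg[1:3]
  b <- seg[4:6]
  dl <- b - a
  B <- c(0, 0, 0)
  for (i in seq_len(n_nodes)) {
    r <- point - (a + gl$x[i] * dl)
    B <- B + gl$w[i] * ms_constants$mu0_4pi * current *
      pracma::cross(dl, r) / sum(r^2)^1.5
  }
  B
}

# quadrature of the point-source potential kernel along one segment
lfp_quadrature <- function(seg, Im, point, sigma_cond = 0.3, n_nodes = 1000) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  a <- seg[1:3]
  b <- seg[4:6]
  dl <- b - a
  phi <- 0
  for (i in seq_len(n_nodes)) {
    r <- sqrt(sum((point - (a + gl$x[i] * dl))^2))
    phi <- phi + gl$w[i] * Im / (4 * pi * sigma_cond * r)
  }
  phi
}
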