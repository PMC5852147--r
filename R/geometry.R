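#' Build a simplified three-branch pyramidal-cell morphology
#'
#' Constructs a "ball-and-stick" stand-in for a CA1 pyramidal cell: a chain of
#' basal-dendrite compartments, a soma compartment, and a chain of
#' apical-dendrite compartments, all collinear along the main dendritic axis
#' `+Y`. The apical and basal branches reach exactly `apical_length` and
#' `basal_length` micrometres from the soma centre, so the total dendritic
#' extent is their sum. The morphology carries everything the line-source
#' forward model needs: compartment endpoints, lengths, axial resistance per
#' length, and tree connectivity.
#'
#' @param apical_length Extent of the apical branch from the soma centre, µm
#'   (reaches into stratum radiatum). Must exceed `soma_length / 2`.
#' @param basal_length Extent of the basal branch from the soma centre, µm
#'   (reaches into stratum oriens). Must exceed `soma_length / 2`.
#' @param n_per_branch Number of equal-length compartments per dendritic
#'   branch; the cell has `2 * n_per_branch + 1` compartments in total.
#' @param r_axial Intracellular axial resistance per unit length, MΩ/µm.
#' @param soma_length Length of the soma compartment, µm.
#'
#' @return A tibble of class `ms_cell` with one row per compartment and
#'   columns `compartment`, `parent` (`NA` for the soma root), `region`
#'   (`"basal"`, `"soma"`, `"apical"`), endpoint coordinates `x0,y0,z0` /
#'   `x1,y1,z1` (µm, start = proximal), `length_um`, `r_axial` and `arc_pos`
#'   (signed cable position of the compartment midpoint relative to the soma
#'   centre, negative on the basal side). The soma index and the unit main
#'   axis are stored as attributes.
#' @examples
#' cell <- build_template_cell(300, 200, n_per_branch = 10)
#' nrow(cell) # 21 compartments
#' @export
build_template_cell <- function(apical_length = 300, basal_length = 200,
                                n_per_branch = 10, r_axial = 0.5,
                                soma_length = 20) {
  check_positive(apical_length, "apical_length")
  check_positive(basal_length, "basal_length")
  check_positive(r_axial, "r_axial")
  check_positive(soma_length, "soma_length")
  if (n_per_branch < 1 || n_per_branch != round(n_per_branch)) {
    abort("`n_per_branch` must be a positive integer")
  }
  hs <- soma_length / 2
  if (apical_length <= hs || basal_length <= hs) {
    abort("branch lengths must exceed half the soma length")
  }

  seg_chain <- function(from, to, n) {
    y <- seq(from, to, length.out = n + 1)
    tibble(y0 = y[-(n + 1)], y1 = y[-1])
  }

  soma <- tibble(
    region = "soma", parent = NA_integer_,
    y0 = -hs, y1 = hs
  )
  apical <- seg_chain(hs, apical_length, n_per_branch)
  apical$region <- "apical"
  basal <- seg_chain(-hs, -basal_length, n_per_branch)
  basal$region <- "basal"

  cell <- dplyr::bind_rows(soma, apical, basal)
  cell$compartment <- seq_len(nrow(cell))
  # apical/basal chains attach to the soma (compartment 1) then to their
  # predecessor within the chain
  n_per_branch <- as.integer(n_per_branch)
  cell$parent <- c(
    NA_integer_,
    c(1L, 1L + seq_len(n_per_branch - 1)),
    c(1L, 1L + n_per_branch + seq_len(n_per_branch - 1))
  )
  cell <- tibble(
    compartment = cell$compartment,
    parent = cell$parent,
    region = cell$region,
    x0 = 0, y0 = cell$y0, z0 = 0,
    x1 = 0, y1 = cell$y1, z1 = 0
  )
  cell$length_um <- abs(cell$y1 - cell$y0)
  cell$r_axial <- r_axial
  cell$arc_pos <- (cell$y0 + cell$y1) / 2
  structure(cell,
    class = c("ms_cell", class(tibble())),
    soma_index = 1L,
    main_axis = c(0, 1, 0)
  )
}

validate_cell <- function(cell) {
  stopifnot(is.data.frame(cell))
  need <- c("compartment", "parent", "region", "x0", "y0", "z0", "x1", "y1", "z1",
            "length_um", "r_axial")
  if (!all(need %in% names(cell))) {
    abort(paste("cell morphology is missing columns:",
                paste(setdiff(need, names(cell)), collapse = ", ")))
  }
  len <- sqrt((cell$x1 - cell$x0)^2 + (cell$y1 - cell$y0)^2 + (cell$z1 - cell$z0)^2)
  if (any(abs(len - cell$length_um) > 1e-9) || any(len <= 0)) {
    abort("compartment lengths must be positive and match endpoint distances")
  }
  check_positive(cell$r_axial, "r_axial")
  if (sum(is.na(cell$parent)) != 1) abort("morphology must have exactly one root")
  invisible(cell)
}

#' Define the layered population layout of an active slice volume
#'
#' Describes the activated subvolume sitting on the diamond sensor: its
#' in-plane footprint, the dead-cell standoff between diamond and the first
#' active cells, the active thickness split into equal Z-layers, and how many
#' cells are seeded per layer. Defaults reproduce the standard stimulated
#' CA1 patch: a 500 x 500 µm footprint, 300 µm of active tissue above a
#' 50 µm dead layer, six 50 µm layers of 1000 cells each (100 cells per
#' 50 µm cube of the soma band, a conservative pyramidal-cell density), and
#' a 50 µm wide soma band along the dendritic axis.
#'
#' @param width_x,length_y Footprint of the active region, µm. The footprint
#'   is centred on the sensor origin.
#' @param active_thickness_d Total active thickness in Z, µm; must be an
#'   exact multiple of `layer_thickness`.
#' @param dead_layer_z0 Thickness of the dysfunctional-cell layer above the
#'   diamond surface, µm; no soma is placed below `z = dead_layer_z0`.
#' @param cells_per_layer Number of cells seeded in each Z-layer.
#' @param layer_thickness Thickness of one Z-layer, µm.
#' @param soma_band_width_y Width of the soma band in Y, µm (the pyramidal
#'   layer); soma Y positions are uniform within it.
#' @return A list of class `ms_layout`.
#' @export
population_layout <- function(width_x = 500, length_y = 500,
                              active_thickness_d = 300, dead_layer_z0 = 50,
                              cells_per_layer = 1000, layer_thickness = 50,
                              soma_band_width_y = 50) {
  check_positive(c(width_x, length_y, active_thickness_d, layer_thickness),
                 "layout dimensions")
  check_positive(dead_layer_z0, "dead_layer_z0", allow_zero = TRUE)
  check_positive(soma_band_width_y, "soma_band_width_y", allow_zero = TRUE)
  if (cells_per_layer < 1 || cells_per_layer != round(cells_per_layer)) {
    abort("`cells_per_layer` must be a positive integer")
  }
  n_layers <- active_thickness_d / layer_thickness
  if (abs(n_layers - round(n_layers)) > 1e-9) {
    abort("`active_thickness_d` must be an exact multiple of `layer_thickness`")
  }
  structure(list(
    width_x = width_x, length_y = length_y,
    active_thickness_d = active_thickness_d, dead_layer_z0 = dead_layer_z0,
    cells_per_layer = as.integer(cells_per_layer),
    layer_thickness = layer_thickness,
    soma_band_width_y = soma_band_width_y,
    n_layers = as.integer(round(n_layers))
  ), class = "ms_layout")
}

#' Place a randomized population of template cells in a layered volume
#'
#' Replicates the template morphology across the layout: each Z-layer
#' receives `cells_per_layer` cells; soma X and Z are uniform within the
#' layer footprint, soma Y is uniform within the soma band, and every cell is
#' rigidly rotated by a uniform random angle about its main dendritic axis
#' `+Y` (relevant for non-collinear morphologies; a straight template is
#' rotation-invariant). Placement is bit-reproducible for a given `seed`.
#'
#' @param layout An [population_layout()].
#' @param template A cell from [build_template_cell()] whose main axis is
#'   `+Y`.
#' @param seed Integer RNG seed.
#' @return A tibble of class `ms_population`: the template compartment table
#'   replicated per cell with positioned coordinates, plus `cell_id` and
#'   `layer` columns. A per-cell summary (soma position and rotation angle)
#'   is stored in the `cells` attribute, the layout and seed in `layout` /
#'   `seed` attributes.
#' @export
place_population <- function(layout, template = build_template_cell(),
                             seed = 1L) {
  stopifnot(inherits(layout, "ms_layout"))
  validate_cell(template)
  axis <- attr(template, "main_axis")
  if (is.null(axis) || max(abs(axis - c(0, 1, 0))) > 1e-12) {
    abort("template `main_axis` must be +Y")
  }
  n_cells <- layout$n_layers * layout$cells_per_layer

  cells <- with_seed(seed, {
    layer <- rep(seq_len(layout$n_layers), each = layout$cells_per_layer)
    z_lo <- layout$dead_layer_z0 + (layer - 1) * layout$layer_thickness
    tibble(
      cell_id = seq_len(n_cells),
      layer = layer,
      soma_x = runif(n_cells, -layout$width_x / 2, layout$width_x / 2),
      soma_y = runif(n_cells, -layout$soma_band_width_y / 2,
                     layout$soma_band_width_y / 2),
      soma_z = z_lo + runif(n_cells) * layout$layer_thickness,
      theta = runif(n_cells, 0, 2 * pi)
    )
  })

  n_comp <- nrow(template)
  idx <- rep(seq_len(n_cells), each = n_comp)
  pop <- template[rep(seq_len(n_comp), times = n_cells), ]
  pop$cell_id <- idx
  pop$layer <- cells$layer[idx]
  ct <- cos(cells$theta[idx])
  st <- sin(cells$theta[idx])
  rot <- function(x, z) list(x = ct * x + st * z, z = -st * x + ct * z)
  p0 <- rot(pop$x0, pop$z0)
  p1 <- rot(pop$x1, pop$z1)
  pop$x0 <- p0$x + cells$soma_x[idx]
  pop$z0 <- p0$z + cells$soma_z[idx]
  pop$x1 <- p1$x + cells$soma_x[idx]
  pop$z1 <- p1$z + cells$soma_z[idx]
  pop$y0 <- pop$y0 + cells$soma_y[idx]
  pop$y1 <- pop$y1 + cells$soma_y[idx]
  pop <- dplyr::relocate(pop, "cell_id", "layer")
  structure(as_tibble(pop),
    class = c("ms_population", class(tibble())),
    cells = cells, layout = layout, template = template, seed = seed
  )
}

#' Draw jittered synaptic-event times for a population
#'
#' Every cell receives the same base stimulation times (default two shocks at
#' 12.5 ms and 37.5 ms, mimicking repeated 40 Hz stimulation of the Schaffer
#' collaterals) jittered by independent Gaussian offsets with standard
#' deviation `sigma`; `sigma = 0.63, 1.56, 3.13` ms span highly synchronous
#' to weakly synchronous drive, with 1.56 ms the default.
#'
#' @param base_times Event times common to all cells, ms.
#' @param sigma Gaussian jitter standard deviation, ms (`>= 0`).
#' @param n_cells Number of cells.
#' @param seed Integer RNG seed.
#' @param region_weights Named fractions of synaptic drive delivered to the
#'   apical (stratum radiatum) and basal (stratum oriens) dendrites; must sum
#'   to 1.
#' @param strength_label One of `"non_spiking"` (0.3 nS-like sub-threshold
#'   drive), `"spiking"` (0.6 nS, the calibrated reference) or `"strong"`
#'   (1.2 nS). Labels map to waveform amplitude scalings of 0.5, 1 and 2.
#' @return A tibble of class `ms_schedule` with columns `cell_id`, `event`,
#'   `time_ms`; parameters are kept as attributes.
#' @export
sample_event_times <- function(base_times = c(12.5, 37.5), sigma = 1.56,
                               n_cells, seed = 1L,
                               region_weights = c(apical = 0.5, basal = 0.5),
                               strength_label = c("spiking", "non_spiking",
                                                  "strong")) {
  strength_label <- match.arg(strength_label)
  check_positive(sigma, "sigma", allow_zero = TRUE)
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (abs(sum(region_weights) - 1) > 1e-9 || any(region_weights < 0)) {
    abort("`region_weights` must be non-negative and sum to 1")
  }
  n_ev <- length(base_times)
  times <- with_seed(seed, {
    matrix(rep(base_times, each = n_cells) +
             rnorm(n_cells * n_ev, 0, sigma), n_cells, n_ev)
  })
  out <- tibble(
    cell_id = rep(seq_len(n_cells), times = n_ev),
    event = rep(seq_len(n_ev), each = n_cells),
    time_ms = as.vector(times)
  )
  out <- dplyr::arrange(out, .data$cell_id, .data$event)
  structure(out,
    class = c("ms_schedule", class(tibble())),
    base_times = base_times, sigma = sigma, seed = seed,
    region_weights = region_weights, strength_label = strength_label
  )
}

#' @export
print.ms_population <- function(x, ...) {
  cells <- attr(x, "cells")
  cat(sprintf("<ms_population> %d cells x %d compartments (%d layers)\n",
              nrow(cells), nrow(x) / nrow(cells),
              attr(x, "layout")$n_layers))
  NextMethod()
}
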