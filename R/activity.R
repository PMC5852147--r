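#' Parametric waveform templates for synaptic and spiking activity
#'
#' The membrane dynamics are represented by parametric templates rather than
#' conductance-based integration: an EPSP is a double-exponential
#' depolarisation delivered to the dendrites, and an action potential (AP) is
#' a stereotyped somatic depolarisation of fixed width fired at a fixed
#' latency after each synaptic event. The corresponding transmembrane
#' currents are built so that the total membrane current of an isolated cell
#' is exactly zero at every instant. Downstream quantities (fields,
#' potentials, dipoles) depend only on the spatiotemporal current
#' distribution, which these templates control directly.
#'
#' Spatial profiles: EPSP depolarisation peaks at the dendritic tips and
#' decays towards the soma with length constant `lambda_epsp`; the AP
#' depolarisation peaks at the soma and decays along both dendrites with
#' length constant `lambda_ap`, which produces the two opposite axial current
#' flows (stratum radiatum to soma, stratum oriens to soma) characteristic of
#' somatic spikes.
#'
#' @param dt Time step, ms.
#' @param duration Trace duration, ms.
#' @param epsp_tau_rise,epsp_tau_decay EPSP rise/decay time constants, ms.
#' @param epsp_amplitude Peak EPSP depolarisation at a dendritic tip, mV.
#' @param ap_amplitude Peak AP depolarisation at the soma, mV.
#' @param ap_width AP full width at half maximum, ms (1.5 ms at the default
#'   35 degree bath temperature).
#' @param ap_latency Delay from synaptic event to AP peak, ms.
#' @param case `"spiking"` (EPSP + AP) or `"non_spiking"` (EPSP only).
#' @param lambda_epsp,lambda_ap Spatial decay constants of the EPSP and AP
#'   depolarisation profiles, µm.
#' @param epsp_current Peak synaptic current per driven compartment, nA.
#' @param ap_current Peak somatic AP sink current, nA.
#' @param v_rest Resting potential, mV.
#' @param strength_scale Multiplier applied to all amplitudes; synaptic
#'   strength labels map here (`non_spiking` 0.5, `spiking` 1, `strong` 2).
#' @param temperature_factor Scales `ap_width` and the EPSP time constants
#'   jointly; temperature enters the templates only through waveform speed.
#' @return A list of class `ms_waveform_params`.
#' @export
waveform_params <- function(dt = 0.025, duration = 60,
                            epsp_tau_rise = 0.5, epsp_tau_decay = 5,
                            epsp_amplitude = 5, ap_amplitude = 100,
                            ap_width = 1.5, ap_latency = 2,
                            case = c("spiking", "non_spiking"),
                            lambda_epsp = 200, lambda_ap = 150,
                            epsp_current = 0.05, ap_current = 0.5,
                            v_rest = -65, strength_scale = 1,
                            temperature_factor = 1) {
  case <- match.arg(case)
  check_positive(c(dt, duration, epsp_tau_rise, epsp_tau_decay, ap_width,
                   lambda_epsp, lambda_ap, temperature_factor, strength_scale),
                 "waveform parameters")
  if (epsp_tau_rise >= epsp_tau_decay) {
    abort("`epsp_tau_rise` must be smaller than `epsp_tau_decay`")
  }
  structure(list(
    dt = dt, duration = duration,
    epsp_tau_rise = epsp_tau_rise * temperature_factor,
    epsp_tau_decay = epsp_tau_decay * temperature_factor,
    epsp_amplitude = epsp_amplitude, ap_amplitude = ap_amplitude,
    ap_width = ap_width * temperature_factor, ap_latency = ap_latency,
    case = case, lambda_epsp = lambda_epsp, lambda_ap = lambda_ap,
    epsp_current = epsp_current, ap_current = ap_current,
    v_rest = v_rest, strength_scale = strength_scale
  ), class = "ms_waveform_params")
}

# temporal kernels -----------------------------------------------------------

# double-exponential EPSP kernel, unit peak, zero for t < 0
kernel_epsp <- function(t, tau_r, tau_d) {
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  out <- ifelse(t > 0, (exp(-t / tau_d) - exp(-t / tau_r)) / norm, 0)
  out
}

# Gaussian AP depolarisation kernel, unit peak, FWHM = width
kernel_ap <- function(t, width) {
  s <- width / (2 * sqrt(2 * log(2)))
  exp(-t^2 / (2 * s^2))
}

# biphasic AP membrane-current kernel (difference of Gaussians: sink then
# delayed source), unit peak magnitude
kernel_ap_current <- function(t, width) {
  s <- width / (2 * sqrt(2 * log(2)))
  exp(-t^2 / (2 * s^2)) - exp(-(t - width)^2 / (2 * s^2))
}

# spatial profiles ------------------------------------------------------------

# EPSP depolarisation profile over compartments: region-weighted exponential
# decay from each dendritic tip towards (and past) the soma
profile_epsp <- function(cell, params, region_weights) {
  if (!"arc_pos" %in% names(cell)) {
    abort("cell morphology must carry `arc_pos` (built by build_template_cell())")
  }
  s <- cell$arc_pos
  tip_ap <- max(s)
  tip_ba <- min(s)
  w <- region_weights[["apical"]] * exp(-(tip_ap - s) / params$lambda_epsp) +
    region_weights[["basal"]] * exp(-(s - tip_ba) / params$lambda_epsp)
  w
}

profile_ap <- function(cell, params) {
  exp(-abs(cell$arc_pos) / params$lambda_ap)
}

# synaptic membrane-current profile: inward (negative) on dendritic
# compartments split by region weight, uniform compensating return over all
# compartments; sums to zero exactly
profile_epsp_current <- function(cell, params, region_weights) {
  w <- numeric(nrow(cell))
  for (r in c("apical", "basal")) {
    i <- which(cell$region == r)
    if (length(i)) w[i] <- -region_weights[[r]] / length(i)
  }
  w <- w - mean(w) # uniform return current
  params$epsp_current * w / max(abs(w))
}

# AP membrane-current profile: somatic sink, dendritic sources weighted by
# the AP depolarisation profile; sums to zero exactly
profile_ap_current <- function(cell, params) {
  w <- numeric(nrow(cell))
  soma <- which(cell$region == "soma")
  dend <- which(cell$region != "soma")
  w[soma] <- -1
  wa <- profile_ap(cell, params)[dend]
  w[dend] <- wa / sum(wa)
  params$ap_current * w
}

# axial-current profiles implied by the Vm templates: parent-difference of
# the spatial profile divided by compartment cable resistance; root = 0
axial_profile <- function(cell, w) {
  p <- cell$parent
  dw <- ifelse(is.na(p), 0, w - w[ifelse(is.na(p), 1, p)])
  dw / (cell$length_um * cell$r_axial)
}

#' Generate template membrane activity for one cell
#'
#' Builds the per-compartment membrane potential `Vm`, transmembrane current
#' `Im` and axial current `I_axial` time courses for a cell receiving
#' synaptic events at the given times, using the parametric templates of
#' [waveform_params()]. Membrane currents sum to zero across compartments at
#' every time point (an isolated cell neither sources nor sinks net
#' current).
#'
#' @param cell A cell morphology (see [build_template_cell()]).
#' @param events Numeric vector of synaptic event times for this cell, ms;
#'   all must lie within `[0, duration]`.
#' @param params A [waveform_params()] object.
#' @param region_weights Fractions of synaptic drive per dendritic region.
#' @param times Optional explicit time base, ms; defaults to
#'   `seq(0, duration, by = dt)`. Supplying a short vector (even a single
#'   frame) evaluates the templates only there, which is what the population
#'   field renderer uses.
#' @return A list of class `ms_activity` with `time_ms`, matrices `Vm` (mV),
#'   `Im` (nA) and `I_axial` (nA), each compartments x time.
#' @export
generate_cell_activity <- function(cell, events, params,
                                   region_weights = c(apical = 0.5, basal = 0.5),
                                   times = NULL) {
  validate_cell(cell)
  stopifnot(inherits(params, "ms_waveform_params"))
  if (is.null(times)) times <- seq(0, params$duration, by = params$dt)
  if (length(events) && (min(events) < 0 || max(events) > params$duration)) {
    abort("synaptic events must lie within [0, duration]")
  }
  n <- nrow(cell)
  Tn <- length(times)
  sc <- params$strength_scale
  spiking <- params$case == "spiking"

  wE <- profile_epsp(cell, params, region_weights)
  wA <- profile_ap(cell, params)
  mE <- profile_epsp_current(cell, params, region_weights)
  mA <- profile_ap_current(cell, params)

  gE <- numeric(Tn)
  gA <- numeric(Tn)
  gAI <- numeric(Tn)
  for (te in events) {
    gE <- gE + kernel_epsp(times - te, params$epsp_tau_rise, params$epsp_tau_decay)
    if (spiking) {
      gA <- gA + kernel_ap(times - te - params$ap_latency, params$ap_width)
      gAI <- gAI + kernel_ap_current(times - te - params$ap_latency, params$ap_width)
    }
  }

  Vm <- params$v_rest +
    sc * params$epsp_amplitude * outer(wE, gE) +
    if (spiking) sc * params$ap_amplitude * outer(wA, gA) else 0
  Im <- sc * outer(mE, gE) + if (spiking) sc * outer(mA, gAI) else 0
  Ia <- compute_axial_currents(cell, Vm)
  structure(list(time_ms = times, Vm = Vm, Im = Im, I_axial = Ia),
            class = "ms_activity")
}

#' Axial currents from compartmental membrane potentials
#'
#' The axial (intracellular) current of compartment `n` is the potential
#' difference to its tree parent divided by the compartment's cable
#' resistance: `I_axial = (Vm_n - Vm_parent) / (length * r_axial)`. The root
#' compartment carries no axial current (no cable above the root). With mV,
#' µm and MΩ/µm this yields nA directly.
#'
#' @param cell A cell morphology.
#' @param Vm Matrix of membrane potentials, compartments x time, mV.
#' @return Matrix of axial currents, compartments x time, nA.
#' @export
compute_axial_currents <- function(cell, Vm) {
  Vm <- as.matrix(Vm)
  if (nrow(Vm) != nrow(cell)) {
    abort("`Vm` must have one row per compartment")
  }
  p <- cell$parent
  root <- which(is.na(p))
  pfill <- ifelse(is.na(p), root[1], p)
  Ia <- (Vm - Vm[pfill, , drop = FALSE]) /
    (cell$length_um * cell$r_axial)
  Ia[root, ] <- 0
  Ia
}

#' Equivalent current dipole of a cell or population
#'
#' Sums axial current times oriented compartment length over all
#' compartments: `Q(t) = sum_k I_axial_k(t) * L_k`, with `L_k` the vector
#' from compartment start to end. This is the far-field source strength of
#' the cell; for synchronously active cells the population dipole is the
#' linear sum of the single-cell dipoles.
#'
#' @param cell A cell morphology (or positioned population slice with the
#'   same columns).
#' @param I_axial Matrix of axial currents, compartments x time, nA.
#' @return A list of class `ms_ecd` with `time` index, matrix `Q` (time x 3,
#'   pA·m) and `peak_magnitude` (pA·m).
#' @export
compute_ecd <- function(cell, I_axial) {
  I_axial <- as.matrix(I_axial)
  if (nrow(I_axial) != nrow(cell)) {
    abort("`I_axial` must have one row per compartment")
  }
  L <- cbind(cell$x1 - cell$x0, cell$y1 - cell$y0, cell$z1 - cell$z0)
  Q <- crossprod(I_axial, L) / 1000 # nA*um -> pA*m
  colnames(Q) <- c("Qx", "Qy", "Qz")
  mag <- sqrt(rowSums(Q^2))
  structure(list(Q = Q, magnitude = mag, peak_magnitude = max(mag)),
            class = "ms_ecd")
}

#' Calibrate waveform amplitudes to a target single-cell dipole
#'
#' Scales all template amplitudes (depolarisations and membrane currents)
#' jointly so that a single calibrated cell firing one action potential
#' attains a peak equivalent-current-dipole magnitude of `target_peak_ecd`
#' (default 0.2 pA·m, the literature value for a pyramidal-cell spike). The
#' dipole is linear in the amplitudes, so the calibration is exact and
#' idempotent.
#'
#' @param params A [waveform_params()] object (case is forced to spiking for
#'   the calibration run; the returned params keep their original case).
#' @param target_peak_ecd Target peak dipole magnitude, pA·m.
#' @param cell Morphology used for calibration.
#' @return `params` with `epsp_amplitude`, `ap_amplitude`, `epsp_current`
#'   and `ap_current` rescaled.
#' @export
calibrate_waveforms <- function(params, target_peak_ecd = 0.2,
                                cell = build_template_cell()) {
  check_positive(target_peak_ecd, "target_peak_ecd")
  probe <- params
  probe$case <- "spiking"
  probe$strength_scale <- 1
  act <- generate_cell_activity(cell, events = 10, params = probe,
                                times = seq(0, 30, by = params$dt))
  peak <- compute_ecd(cell, act$I_axial)$peak_magnitude
  if (peak <= 0) abort("calibration trace produced no dipole")
  fac <- target_peak_ecd / peak
  for (f in c("epsp_amplitude", "ap_amplitude", "epsp_current", "ap_current")) {
    params[[f]] <- params[[f]] * fac
  }
  params
}

#' Population equivalent current dipole time course
#'
#' Sums the template dipole waveform over all cells and events of a
#' schedule. Because all cells share the template (rotation about the
#' dendritic axis leaves the dipole unchanged), the population dipole is a
#' shifted-kernel superposition, which is used both for validation against
#' single-cell linearity and to locate the population activity peak.
#'
#' @param population An `ms_population` (only the cell count is used).
#' @param schedule An `ms_schedule` of per-cell event times.
#' @param params Calibrated [waveform_params()].
#' @param times Time base, ms.
#' @return An `ms_ecd` for the whole population.
#' @export
population_ecd <- function(population, schedule, params,
                           times = seq(0, params$duration, by = params$dt)) {
  template <- attr(population, "template")
  rw <- attr(schedule, "region_weights") %||% c(apical = 0.5, basal = 0.5)
  # single-cell dipole response to one event at t = 0
  base <- generate_cell_activity(
    template, events = 0,
    params = `[[<-`(params, "duration", max(times) + 1),
    region_weights = rw,
    times = seq(-1, max(times) + 1, by = params$dt)
  )
  q1 <- compute_ecd(template, base$I_axial)$Q
  tt <- base$time_ms
  Q <- matrix(0, length(times), 3, dimnames = list(NULL, colnames(q1)))
  for (te in schedule$time_ms) {
    idx <- round((times - te - tt[1]) / params$dt) + 1
    ok <- idx >= 1 & idx <= length(tt)
    Q[ok, ] <- Q[ok, ] + q1[idx[ok], ]
  }
  mag <- sqrt(rowSums(Q^2))
  structure(list(Q = Q, magnitude = mag, peak_magnitude = max(mag),
                 time_ms = times),
            class = "ms_ecd")
}
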