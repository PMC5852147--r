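---
title: "Modeling opto-magnetic imaging of brain-slice activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling opto-magnetic imaging of brain-slice activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magslice)
```

## The problem

Wide-field NV-diamond magnetometry can in principle image the magnetic
fields that synchronous neural activity generates at the surface of an
acute brain slice, at sub-nanotesla field strengths and tens-of-µm pixel
sizes. Whether that is *useful* depends on three quantitative questions
that this package answers by simulation and analysis:

1. how strong and how spatially structured are the fields of a driven
   hippocampal CA1 patch at the diamond surface;
2. how fast must the sensor sample to preserve the evoked waveforms;
3. given a sensor noise level and pixel size, how well can the underlying
   axial current density be reconstructed — what resolution, and at what
   signal-to-noise?

## Coordinates and units

The diamond surface is the plane `z = 0`; the slice occupies `z > 0`; `Y`
is the dendritic axis of the pyramidal cells, `X` the slice width. All
lengths are µm, time ms, currents nA, potentials mV, fields nT, axial
resistances MΩ/µm. In these units Ohm's law is unit-free and
`mu0/4pi = 0.1 nT·µm/nA` exactly, so no intermediate quantity strays far
from unity — SI metres and teslas would put the Biot–Savart prefactor at
1e-7 and fields at 1e-9, inviting underflow and unreadable code.

## Synthetic sources

The generator emulates electrical stimulation of the Schaffer collaterals
driving a 500 × 500 × 300 µm CA1 subvolume that rests on the sensor
behind a 50 µm layer of dead cells:

* **Morphology.** A parametric three-branch stand-in (basal chain — soma —
  apical chain, default 200/20/300 µm, 10 compartments per branch) rather
  than a reconstructed multi-compartment morphology. The downstream
  quantities (fields, potentials, dipoles) depend only on the
  spatiotemporal distribution of compartment currents, which the
  templates control directly; channel biophysics is out of scope.
* **Population.** Six 50 µm layers of 1000 cells each — a deliberately
  conservative density of 100 cells per 50 µm cube of the soma band
  (literature counts suggest 2–3×more); field strengths rescale linearly
  with density if a different value is preferred. Somata are uniform in
  X and Z within their layer and within a 50 µm Y-band; each cell is
  rotated by a uniform angle about its dendritic axis. Placement is
  bit-reproducible given the seed.
* **Drive.** Every cell receives the same base events (12.5 and 37.5 ms,
  mimicking 40 Hz paired stimulation) jittered by N(0, σ²) with
  σ = 1.56 ms by default; σ = 0.63 and 3.13 ms span high and weak
  synchrony. Synaptic strength enters as a label
  (`non_spiking`/`spiking`/`strong` → amplitude scale 0.5/1/2), not as a
  conductance.
* **Dynamics.** Template waveforms replace cable integration: an EPSP is
  a double-exponential depolarisation (τ_rise 0.5 ms, τ_decay 5 ms)
  peaking at the dendritic tips and decaying towards the soma
  (λ = 200 µm); an action potential is a Gaussian somatic depolarisation
  of 1.5 ms FWHM (a 35 °C value; temperature enters only as a joint
  width/τ scale factor) decaying along the dendrites (λ = 150 µm), fired
  2 ms after each synaptic event. Membrane currents are built
  conservation-exact: synaptic inward current on the dendrites with a
  uniform return over all compartments, and a biphasic
  (difference-of-Gaussians) somatic sink with dendritic sources for the
  spike; `colSums(Im)` is zero to 1e-15 nA by construction. The somatic
  spike profile produces the two opposite axial current flows (apical →
  soma and basal → soma) that give the characteristic B_X sign flip
  across the soma band.
* **Calibration.** All amplitudes are scaled jointly so that one cell
  firing one action potential peaks at an equivalent current dipole of
  0.2 pA·m — the literature anchor for a pyramidal-cell spike. The
  calibration is linear, hence exact and idempotent. 200 synchronised
  calibrated cells yield exactly 40 pA·m by linearity; reconstructed
  multi-compartment models reach ~35 pA·m for the same count, the gap
  being a morphology effect that a stick model cannot (and does not try
  to) reproduce.

What passing tests on these sources do *not* show: real slices have
heterogeneous morphologies, partial recruitment, conduction delays and
active dendrites. The generator's purpose is to give the forward and
inverse machinery sources with the right calibrated dipole scale, spatial
organisation and temporal structure — order-of-magnitude field
predictions (the test suite asserts the default spiking scenario lands
within a factor of 3 of the 1.5 nT reference peak) rather than exact
waveforms.

## Forward model

Compartment currents map to sensor-plane fields by exact finite-segment
line sources: the Biot–Savart closed form for the magnetic field of each
straight segment carrying its axial current, and the standard line-source
kernel for the extracellular potential of each segment's membrane current
in an infinite homogeneous conductor (σ = 0.3 S/m by default, a common
slice value; φ scales as 1/σ). Fields of all cells superpose linearly.
Field points closer than 1e-3 µm to a segment axis are an error — field
evaluations belong at physical distances from the membrane, not at the
cable centreline.

Pixelation averages the field over an n × n sub-grid per pixel
(default 4; averaging only matters when the pixel is comparable to the
source distance, e.g. 2 µm pixels against a cell 1 µm away — at 50 µm
pixels and 50 µm standoff it is a sub-percent effect, and the large
population runs in the test suite use pixel-centre sampling).

The finite extracellular volume conductor attenuates B_X; this is
represented by the depth-dependent scaling `s(d) = a1 + a2/(d + c)`
applied to B_X only (B_Z and φ are essentially unaffected). The
coefficients come from external electromagnetic (FEM) fits that are not
part of this package; the default is the identity (`a1 = 1, a2 = 0`),
and fitted values can be supplied via `volume_correction()`.

For population work the renderer exploits that every compartment current
is a fixed spatial profile times one of two shared temporal kernels
(EPSP, AP): the field factorises into per-cell geometric couplings times
kernel activations, reducing a full 6000-cell, 240-frame rendering to one
pass over (pixel, segment) pairs plus matrix products. The factorised
path equals the direct per-frame superposition to machine precision and
is property-tested against it.

## Temporal bandwidth

Evoked transients are characterised by the cumulative fraction of signal
power below each frequency (Hann-windowed periodogram; DC excluded, since
a constant offset is sensor calibration, not dynamics). "Most of the
power" is not a standard number; the package default is 0.95, exposed as
a parameter. The recommended sampling rate is twice the 95%-power
frequency. Filtering uses a third-order Butterworth low-pass (maximally
flat pass band, half-power at f_c), causal by default to match an
acquisition chain, zero-phase behind a flag. Note that filtering *at*
the 95%-power frequency necessarily discards ~5% of power — an RMS error
of ~22% of the AC signal — so waveform-preservation claims are asserted
at twice that cut-off, where the error falls below 10%.

## Wiener reconstruction and its conventions

For resolution analysis the source is idealised as a point in the sensor
plane, uniformly extended from `z0` to `z0 + d` in depth with strength
`sigma_j` (nA), so its 2D spectrum is flat. The measured B_X is then the
source convolved with a radially symmetric low-pass kernel whose spectrum
`f(k)` has the closed form given in `transfer_function()`; its cut-off
falls with standoff and with slab depth. Numerical conventions that
matter:

* **k-grid.** Angular spatial frequencies on the FFT grid of the sensor,
  band `[-pi/Delta, pi/Delta]²`; FoV-periodic boundaries. `f(0)` uses the
  analytic limit (the printed closed form is 0/0 there). The large-`k`
  factor is evaluated as `exp(-z0 k)(1-exp(-d k))/(2k)` to avoid
  `sinh` overflow.
* **Correction grouping.** With a non-identity volume correction, the
  `E1` terms are implemented exactly as grouped in the closed form above.
  Direct z-integration of the corrected integrand would place an extra
  `exp(ck)` factor on the `E1` terms; the two groupings agree only as
  `ck → 0`. The implementation follows the stated closed form, and the
  brute-force Fourier oracle comparison is therefore exact only for the
  identity correction (`a2 = 0`), which is also the only configuration
  the quantitative claims use.
* **Calibration.** `calibrate_source_strength()` matches the *continuous*
  peak field `B(0) = sigma_j (1/2π)∫ f(k) k dk` to the target (1.5 nT for
  the slice scenario, 2.5 nT for the planar one). A pixelated sensor then
  records slightly less than the target when the field varies on
  sub-pixel scales — which is the physically meaningful convention: the
  calibration anchors the source, not the sensor. For the slice scenario
  the two conventions differ by <1%; for the planar source (z0 = 1 µm
  against 2 µm pixels) pixel-peak calibration would inflate `sigma_j` by
  ~50% and distort the noise threshold.
* **Regularisation vs noise propagation.** The Wiener filter uses the
  regularisation ratio `eta² A_FoV / sigma_j²` — equivalently a source
  power spectral density normalised per unit field-of-view area,
  `s_j = sigma_j²/A_FoV`, against the per-pixel white-noise PSD
  `s_eta = eta²`. The *reconstruction noise*, and hence the pSNR, is
  propagated with that same physical per-pixel PSD:
  `var = (1/2π)² ∫∫ |f_I|² eta² dk`, identically equal to pushing white
  pixel noise of std `eta/Delta` through the filter. The seeded
  Monte-Carlo route (`psnr(..., "monte_carlo")`) is the independent
  check and agrees with the analytic route within sampling error. Mixing
  the conventions — using `eta² A_FoV` as the propagation PSD — would
  overstate the reconstruction noise by a factor `sqrt(A_FoV)` (1000 for
  a 1 mm² FoV) and is the one pitfall of this algebra; the package's
  split reproduces the anchor results (pSNR ≈ 10 at `eta = 10 nT·µm` for
  the slice scenario) where the mixed reading misses them by three
  orders of magnitude.
* **PSF and FWHM.** The PSF is `sigma_j · IFT{ f²/(f² + eta²A_FoV/σ_j²) }`
  band-limited to the sensor band (the band-limit *is* the pixel sinc
  kernel of the sampling). FWHM is measured on the X-axis cut through
  the peak with linear interpolation; an azimuthally averaged profile is
  available (`profile = "radial"`) and agrees for these radially
  symmetric PSFs — the axis cut is the default because the pixel kernel
  is separable in X/Y. In the zero-noise limit the PSF is the discrete
  band-limited delta, whose interpolated FWHM is exactly one pixel (the
  continuum sinc value is 1.21 pixels; the sinc zeros fall on the grid).
* **Thresholds.** "The noise level at which pSNR reaches 10" is found by
  bisection on log η to 1% (`eta_for_psnr()`); pSNR is strictly monotone
  in η.

Applied to the slice scenario (z0 = 50 µm, d = 300 µm, 1.5 nT
calibration, 1 mm² FoV, 128 × 128 pixels) the acceptance script computes
a pSNR-10 threshold of 9.7 nT·µm and a PSF FWHM of 155 µm at
η = 10 nT·µm; the planar scenario (z0 = 1 µm, d = 2 µm, 2.5 nT, 2 µm
pixels) thresholds at 0.50 nT·µm. With the identity volume-conductor
correction these FWHM figures are what the printed transfer function
yields under the stated calibration; supplying fitted correction
coefficients changes the kernel shape and therefore the achievable
resolution, which is exactly why the correction is a first-class input
rather than a constant.

## Sensitivity calculus

`volume_sensitivity()` implements the ensemble shot-noise limit
`eta_V = (h/gµB) / (C sqrt(eps n_NV T2*))` with the gyromagnetic constant
fixed at 28 Hz/nT and the ppm→µm⁻³ conversion at 1.76e5 (carbon density
of diamond). The conversions to area- and pixel-normalised noise are
exact algebra and dimensionally round-trip by construction.
`trials_to_reach()` returns the exact ceiling of the √N averaging law —
(481/10)² → 2312 trials — rather than a rounded figure, leaving
presentation rounding to the caller.

## Problem sizes and determinism

Default analyses run on: 128² (slice) and 512² (planar) reconstruction
grids; 6000-cell populations rendered on a 20 × 20, 1 mm² sensor grid at
0.25 ms frames; 500 Monte-Carlo noise realisations for the pSNR
cross-check; 2¹⁸ samples for the band-limited-noise spectral check.
These sizes keep the whole suite in the minutes range on one CPU while
leaving every quantitative conclusion grid-converged (the PSF FWHM, for
instance, changes by <0.1% under 4× and 8× zero-padding). Every
stochastic step takes an explicit integer seed and restores the caller's
RNG state; rerunning any scenario configuration is bit-identical, and
scenario bundles embed their configuration hash, seeds and package
version.

## Known limitations

* Stick morphologies and template dynamics: no cable propagation, no
  conductance synapses, no spike-failure; population waveforms are
  smoother than reality at high frequencies, so bandwidth
  recommendations from the synthetic sources are indicative, not
  prescriptive.
* Infinite homogeneous volume conductor for φ and, by default, for B_X
  (identity correction); no FEM modelling.
* 2D reconstruction only: the slab transfer function projects depth
  away, and no depth-resolved (3D) inversion is attempted.
* Reconstruction is from B_X alone; B_Z or joint-component inversions
  are not implemented.
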