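Package: magslice
Title: Forward Modeling and Wiener Reconstruction for Opto-Magnetic Imaging of Brain-Slice Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the neural magnetic fields and local field potentials
    that a nitrogen-vacancy (NV) diamond magnetometer would record beneath an
    acute brain slice, and analyses what such a sensor can resolve. Provides a
    synthetic generator for populations of simplified pyramidal cells with
    jittered synaptic drive, an exact finite-segment line-source forward model
    for the magnetic field and extracellular potential on a pixelated sensor
    plane, temporal bandwidth analysis (cumulative power, Butterworth
    filtering, Nyquist rates), an analytic spatial-frequency transfer function
    for a uniformly active slab, Wiener-deconvolution reconstruction of the 2D
    axial current density with point-spread-function, FWHM and peak-SNR
    characterisation, and the NV-sensor sensitivity calculus linking
    volume-normalised sensitivity to area- and pixel-normalised noise and
    trial-averaging requirements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
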