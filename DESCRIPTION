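Package: tremorlock
Title: Phase-Stability Analysis of Rhythmically Stimulated Physiological Tremor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying entrainment of physiological tremor by
    rhythmic (transcranial alternating current or photic) stimulation from
    tri-axial accelerometry. Implements the phase-synchronization-index (PSI)
    pipeline: principal-component reduction, Thomson multitaper spectral peak
    detection, zero-phase Butterworth band-pass filtering, Hilbert
    instantaneous phase and amplitude, Box-Cox variance stabilization,
    phase-difference likelihood histograms, phase-stability profiles over a
    0-20 Hz reference grid, and sham-baselined percent change with group-level
    contrasts. Includes a stochastic phase-oscillator simulator of tremor
    accelerometry with controllable coupling to the stimulation waveform, and
    a quasi-static finite-volume current-density solver on voxel phantoms
    (Laplace equation with isotropic tissue conductivities, electrode pads,
    and 1 mA source scaling).
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
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    RNifti,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
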