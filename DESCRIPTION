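Package: measens
Title: Lead-Field Sensitivity and Impedance Simulation for Microelectrode
    Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finite-element simulation of electric bioimpedance measurements
    on planar microelectrode arrays (MEAs). Solves the quasi-static
    complex-conductivity field problem with constant-phase-element electrode
    interfaces (complete electrode model) and a thin-layer cell membrane,
    computes lead fields and Geselowitz sensitivity distributions of two- and
    four-electrode constellations, volume-averaged normalized sensitivities
    for a cell scanned over the array, and direct impedance spectra with and
    without a cell, including baseline-normalized spectra, impedance loci and
    cell-position sweeps. Includes a graded structured tetrahedral mesher,
    equivalent-circuit spectrum fitting, and export of fields and spectra to
    VTU and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
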