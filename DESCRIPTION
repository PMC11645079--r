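Package: metafcs
Title: Dual-Wavelength On-Chip Metalens Design and Single-Molecule
    Fluorescence Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs segmented dual-wavelength metalenses on silicon nitride
    waveguides by phase-matching the accumulated guided-wave phase to a
    hyperbolic lens phase, simulates their three-dimensional focal fields
    with a band-limited scalar angular-spectrum method, evaluates molecule
    detection efficiency, effective detection volume, and the per-molecule
    photon budget for epi-fluorescence sensing, and simulates fluorescence
    correlation spectroscopy of Brownian molecules with a multi-tau
    correlator and 3D-diffusion model fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
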