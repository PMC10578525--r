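Package: springrio
Title: Spiral-Ring Turbo Spin-Echo Simulation with Concomitant-Field Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for 2D annular spiral-ring turbo
    spin-echo (TSE) MRI with compensation of concomitant (Maxwell) gradient
    fields and B0 inhomogeneity, aimed at low-field (0.55T-1.5T) protocols.
    Generates slew- and amplitude-constrained spiral-ring echo trains with a
    self-retraced central ring, applies sequence-based Maxwell compensation
    (crusher balancing, bipolar pairs with polarity reversal), simulates TSE
    signal pathways with the extended phase graph formalism and multi-echo
    k-space data on digital phantoms, and reconstructs with density-compensated
    adjoint transforms, Chebyshev conjugate-phase correction of concomitant and
    off-resonance phase, and semiautomatic field-map deblurring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    RNifti,
    optparse
Config/testthat/edition: 3
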