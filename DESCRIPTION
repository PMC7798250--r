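Package: areakin
Title: Membrane-Area Scaling for Multi-Compartment Kinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and analysing compartmentalised kinetic
    ODE models in which trans-membrane transport rates scale with the
    interface membrane area rather than with compartment volumes.
    Provides shape-based compartment geometry (spheres, cuboids),
    amount-based ODE assembly under three scaling regimes
    (single-compartment, volume-scaled, area-scaled), deterministic
    time-course integration and equilibrium metrics, scaled sensitivity
    coefficients, a two-cell root epidermis transport comparison across
    developmental zones, and a volume-to-area kinetic-law rescaling
    stage for SBML models with behaviour preservation at a reference
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    Matrix
Config/testthat/edition: 3
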