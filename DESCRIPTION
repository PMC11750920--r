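Package: lungwash
Title: Compartmental Lung Simulator for Multi-Breath Inert-Gas Washout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a Weibel-scaled, optionally asymmetric branched airway
    network of 251 well-mixed airway units, simulates one-dimensional
    convection-diffusion tracer transport over repeated breaths using the
    electrical RC-network analogy (compartment volumes as capacitances,
    diffusive links as resistors, convective transport as upwind-switched
    current sources), and derives multi-breath washout statistics: per-breath
    expiratory curves, phase-3 slopes, normalized phase-3 slopes, and
    inter-unit mean concentration differences between parallel lung units.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
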