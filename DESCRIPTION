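Package: tjbarrier
Title: Dynamic Tight-Junction Barrier Models of Epithelial Permeability and Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic models of the epithelial tight-junction (TJ) leak
    pathway. Bicellular TJ strands are represented as a two-dimensional brick
    lattice of compartments whose strand sections break and reseal as a
    two-state Markov process; the same structural dynamics drive a
    multi-compartment diffusion model of paracellular molecular permeability
    and a dynamic resistor-network model of transepithelial electrical
    resistance (TER), each combined with a static tricellular pore pathway.
    Includes hindered-diffusion slit and pore factors, calibration of the
    break-forming probability and strand resistance to measured permeability
    and TER, steady-state comparator models, strand-number sweeps, and
    parameter sensitivity analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
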