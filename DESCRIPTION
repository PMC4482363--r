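Package: nfkbsim
Title: Spatial Agent-Based Simulation of IL-1/NF-kB Signalling with
    Cytoskeletal Sequestration of IkBa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, configurable three-dimensional particle simulator of
    IL-1 receptor (IL-1RI/TILRR) activation of NF-kB.  Molecules are agents
    performing Brownian motion inside a spherical cell with a nested
    nucleus; reactions fire when partners meet within calibrated
    interaction radii.  The model covers receptor-adapter recruitment
    (MyD88, PI3K) and the kinase cascade to IKK, IkBa phosphorylation and
    degradation, NF-kB nuclear shuttling with delayed transcriptional
    feedback, the PI3K/Akt/Caspase-3 anti-apoptotic branch, and
    sequestration and stimulated release of IkBa on cytoskeletal binding
    sites (passive Kon/Koff exchange plus dissociator-mediated active
    release).  Ships named scenarios for steady state, dissociation
    regimes, fast/slow exchange, TILRR variant panels, expression and dose
    scans, together with well-mixed deterministic and stochastic reference
    solvers used to validate the engine's kinetics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    yaml,
    readr,
    stats,
    utils,
    deSolve,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
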