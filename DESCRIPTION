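Package: ptpkit
Title: Equilibrium Binding, Kinetics and Motif Analysis for Phosphatase Substrate Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantitative studies of pSer/pThr-modulated
    substrate recognition by protein tyrosine phosphatases such as SHP2. Implements
    exact two-component (quadratic) and three-component (cubic) equilibrium models
    for direct and competitive fluorescence-polarization titrations with nonlinear
    Kd fitting; Monte-Carlo propagation of fit uncertainty into Kd ratios with a
    delta-method cross-check; Michaelis-Menten initial-rate analysis and
    integrated progress-curve simulation and fitting for phosphatase mutants,
    including enzyme-equalization multipliers; consensus-motif scanning of protein
    sequences for pSer/pThr-flanked phosphotyrosine sites with phosphosite,
    conservation and domain filters plus position-frequency and charge-enrichment
    statistics; ensemble distance-restraint statistics and a docking restraint
    table writer; and seeded synthetic-data generators emulating every assay so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
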