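Package: viabsim
Title: Continuum Modelling and Parameter Estimation of In Vitro Cancer
    Cell Viability Under Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth and drug-induced death of adherent cancer
    cell cultures with a two-phase avascular continuum model: a nondimensional
    cell-concentration equation (saturating oxygen-dependent growth and death
    terms) coupled to a quasi-steady reaction-diffusion equation for oxygen on
    a two-dimensional grid initialized from a microscopy image. Provides
    sum-of-squares parameter estimation against impedance-based (RTCA)
    normalized cell-index time series and Annexin V/PI flow-cytometry
    viability fractions via multistart bounded quasi-Newton search refined by
    Nelder-Mead, one-at-a-time sensitivity analysis of the fitted parameters,
    a synthetic-data generator with known ground truth for recovery studies,
    and a command-line pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    lhs,
    Matrix,
    optparse,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
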