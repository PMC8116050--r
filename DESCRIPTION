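Package: mcaspolarity
Title: Mass-Conserved Activator-Substrate Models of Cell Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mass-conserved
    activator-substrate (MCAS) reaction-diffusion models of Rho-GTPase cell
    polarity. Implements a minimalistic two-species model, an
    indirect-substrate extension, and mechanistic models of the budding-yeast
    Cdc42/Bem1-GEF circuit with and without negative feedback via GEF
    phosphorylation; integrates them with an adaptive IMEX (implicit
    diffusion, explicit reaction) finite-difference scheme on 1D and 2D grids
    with insulated subdomains; detects and tracks activator peaks to measure
    competition times and classify competition, coexistence and equalization
    outcomes; sweeps outcome phase diagrams and basal-substrate predictors;
    and simulates fluorescence recovery after photobleaching (FRAP) by pure
    diffusion in a 3D two-lobed cell geometry with exponential curve fitting
    of recovery traces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
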