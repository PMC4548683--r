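Package: attenuate
Title: Column and Site-Scale Modelling of Natural Attenuation in Groundwater
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying monitored natural attenuation of dissolved
    chlorinated solvents such as 1,1,1-trichloroethane. Simulates
    one-dimensional saturated column transport with advection, dispersion,
    kinetic linear sorption and first-order biodegradation; analyses
    conservative tracer breakthrough (conductivity calibration, temporal
    moments, dispersivity and porosity estimation); estimates sorption and
    biodegradation rate constants from paired sterile/biotic column
    breakthrough curves with bootstrap intervals; and forecasts a site plume
    with a steady finite-difference groundwater flow model and an explicit
    upwind reactive transport scheme. A synthetic-data module generates
    column, tracer and site data sets with recorded ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
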