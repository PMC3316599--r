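Package: terriforage
Title: Territorial Central-Place Foragers: Simulation, Space-Use Theory and
    Scent-Time Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lattice agent-based simulation of territorial random walkers with
    central-place attraction and scent-mediated conspecific avoidance, together
    with the reduced adiabatic analytic models of animal space use in one and
    two dimensions. Territory borders emerge as slowly fluctuating interfaces
    whose mean square displacement saturates under central-place bias; the
    package builds the saturation-MSD calibration surface, evaluates the
    steady-state border, conditional and marginal densities, and implements the
    inference programme that recovers the active scent time (the period over
    which conspecifics avoid a scent mark) from animal relocation data. Also
    included: 95% probability-mass home-range radii, buffer-zone and
    exclusive-area-fraction geometry for hexagonally packed territories, and a
    quantitative comparison with the Moorcroft-Lewis reaction-diffusion
    territory model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
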