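Package: carrtdex
Title: Predator-Prey Modelling of CAR T-Cell Therapy Under Dexamethasone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the interaction of chimeric antigen receptor
    (CAR) T-cells and glioblastoma tumor cells in the presence of the
    glucocorticoid dexamethasone. Implements a nonautonomous two-species
    predator-prey system in which dexamethasone clears exponentially and
    modulates the effective tumor growth rate, carrying capacity, and CAR
    T-cell death rate. Provides numerical simulation of cell-index
    trajectories, time-resolved stability analysis of the coexistence
    equilibrium with Hopf-bifurcation detection, staged parameter estimation
    from impedance cell-killing-assay time series by particle swarm
    optimization followed by Levenberg-Marquardt refinement, a synthetic
    assay-data generator reproducing the experimental design grid, and a
    treatment success/failure classifier based on the ratio of CAR T-cell
    death to proliferation/exhaustion rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
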