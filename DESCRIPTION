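Package: cdinclusion
Title: Cyclodextrin Inclusion Complexation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing host-guest inclusion complexation of poorly
    soluble drugs with cyclodextrins. Implements Higuchi-Connors phase-solubility
    diagram classification (A_L/A_p) and stability-constant estimation (log-log
    stoichiometry, slope-based K1:1, linearized and nonlinear 1:1/1:2 fits),
    Boltzmann occupancy ratios and Arrhenius rate-ratio estimates between
    complexation states, potential-of-mean-force reconstruction from steered
    pulling work ensembles via the Jarzynski equality (with a second-order
    cumulant alternative and jackknife uncertainties), and centroid-distance
    trajectory statistics with complexation-state classification. A synthetic
    data module generates phase-solubility datasets, Brownian constant-velocity
    pulling work curves, and piecewise-Gaussian distance trajectories so every
    analysis is testable end to end without laboratory or simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
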