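Package: sylvacost
Title: Carbon Sequestration Cost Analysis for Collectively Owned Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for the economics of forest carbon
    sequestration in collectively owned forests. Implements an
    opportunity-cost net-present-value model of the equilibrium carbon
    price over forest rotations (with a volume-biomass-NPP conversion of
    stand growth to annual carbon uptake), Gaussian kernel density
    estimation of the cross-province cost distribution, a small LSTM
    network for recursive cost forecasting, and spatial panel
    econometrics: weight matrix construction, Lagrange-multiplier tests
    for spatial dependence, quasi-maximum-likelihood estimation of the
    spatial Durbin model with fixed effects, and direct/indirect effect
    decomposition with simulation-based inference. A seeded synthetic
    panel generator with known ground truth supports end-to-end testing
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
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
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
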