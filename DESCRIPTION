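Package: phenorisk
Title: Temperature-Driven Insect Phenology Models and Climatic Pest Risk Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building temperature-driven phenology models for
    poikilotherm pests from constant-temperature cohort life-table data, and
    for projecting population growth potential over real or gridded climates.
    Fits the five standard thermal sub-models (cumulative logit
    development-time distributions, the modified four-parameter
    Sharpe-DeMichele development-rate model, the Wang temperature-mortality
    curve, an exponential-polynomial total-fecundity curve, and a Gamma
    age-specific oviposition schedule), runs a stochastic cohort-updating /
    rate-summation life-table simulation under constant or diurnally
    fluctuating temperatures to estimate the six classical demographic
    parameters (GRR, Ro, rm, lambda, T, Dt), and computes the establishment
    risk index (ERI), generation index (GI) and activity index (AI) per
    location or over gridded monthly climatologies, including change maps
    between two climates. Includes a synthetic-data generator for cohort
    observations, weather series and climate grids, and a reference
    parameterization for Spodoptera litura reared on soybean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
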