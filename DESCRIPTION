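Package: carafa
Title: Three-Layer Analysis of Carabid Assemblages, Body Traits and
    Fluctuating Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for analysing ground-beetle (Carabidae)
    responses to forest management at three levels of biological
    organisation: assemblage composition via partial canonical
    correspondence analysis with restricted (cyclic-shift) permutation
    tests, forward selection and passively projected trait summaries
    (community-weighted means, Rao's quadratic entropy); body-trait
    modelling of head width against wing morphology, treatment and body
    size with linear mixed and Bayesian regression models; and
    developmental instability quantified by a directional-asymmetry
    corrected index of fluctuating asymmetry, guarded by a
    trait-suitability gating procedure that screens measurement error,
    antisymmetry, directional asymmetry and size dependence. A synthetic
    data generator with separable asymmetry components provides
    parameter-recovery and calibration tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vegan,
    permute,
    lme4,
    car,
    emmeans,
    rjags,
    coda,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
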