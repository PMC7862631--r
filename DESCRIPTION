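Package: coexipm
Title: Coupled Climate-Driven Integral Projection Models for Two
    Interacting Shrub Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing climate- and density-dependent
    integral projection models (IPMs) of two interacting semiarid shrub
    populations. Provides a synthetic demographic-census generator with the
    full generative structure assumed by the downstream analyses (plot random
    effects, logit-Bernoulli survival with quadratic size, Gaussian growth,
    logit-Bernoulli or ordinal flowering, Poisson seedling counts allocated to
    adults), generalised linear mixed-model fitting with AIC-based model
    selection for the four vital rates, midpoint-rule discretised IPM kernels
    and deterministic growth rates, a coupled two-species dynamic IPM with
    per-iteration cover feedback, and stochastic climate/recruitment scenario
    simulation of stochastic population growth rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmmTMB,
    lme4,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
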