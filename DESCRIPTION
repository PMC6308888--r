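Package: salocc
Title: Hierarchical Occupancy, Abundance and Co-Occurrence Models for
    Repeated Wildlife Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood fitting of single-season site-occupancy
    models (zero-inflated binomial), N-mixture abundance models (Poisson
    mixture over latent abundance with binomial counts), and two-species
    co-occurrence models under the conditional psi_Ba parameterization,
    for detection/non-detection and count matrices from temporally
    replicated surveys of unmarked animals. Includes AIC/AICc multi-model
    inference (Akaike weights, model-averaged effect sizes with
    unconditional intervals, model-averaged predictions), parametric
    bootstrap goodness-of-fit with the overdispersion statistic c-hat,
    derived availability and temporary-emigration decomposition of
    detection, density extrapolation, covariate utilities (Beers aspect
    transformation, topographic-position-index scale selection), and a
    seeded synthetic-data generator emulating a 40-site by 4-visit
    woodland-salamander survey design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
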