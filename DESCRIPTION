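Package: germtime
Title: Thermal, Hydro and Hydrothermal Time Models for Seed Germination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-based threshold models for seed germination
    time courses. Implements the forward thermal-time, hydrotime and
    hydrothermal-time models with a normal distribution of base water
    potentials across the seed lot, the repeated probit regression
    machinery that estimates the hydrotime and hydrothermal time
    constants, the median base water potential and its standard
    deviation, cardinal temperature estimation from germination-rate
    regressions, the classical germination and seedling-vigor indices
    (germination percentage and energy, mean germination time and rate,
    germination index, germination rate index, Timson index, vigor
    indices, moisture content), and a seedable Monte-Carlo generator of
    interval-censored germination experiments for validating every
    fitting stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
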