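Package: thermacclim
Title: Thermal Acclimation of Leaf Gas Exchange and Seasonal Carbon Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing thermal acclimation of photosynthesis and dark
    respiration along temperature gradients. Fits parabolic assimilation-
    temperature and exponential respiration-temperature response curves,
    derives thermal breadth, regresses fitted traits on antecedent air
    temperature, and propagates the resulting acclimation functions through a
    coupled soil-plant-atmosphere (SPAC) leaf gas-exchange and energy-balance
    model to season-integrated carbon budgets. Includes a differential-
    evolution MCMC calibrator with Gelman-Rubin diagnostics and a synthetic-
    data generator emulating a multi-site transplant experiment so the whole
    chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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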