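Package: internodesim
Title: Temperature-Sensitive Internode Growth Simulation for Greenhouse Cucumber
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Daily time-step simulation of internode appearance and elongation
    in greenhouse cucumber, driven by a normalized Arrhenius-type temperature
    response that multiplies developmental rates and divides durations, coupled
    to a light-quantity response for final internode length. Includes
    rank-specific environmental signal windows (PAR4d, T4d), a scenario
    comparison framework (temperature-sensitive vs fixed-20 degree model) with
    light/temperature attribution of length differences, evaluation statistics
    (RMSD, bias, systematic prediction error, CV), and a synthetic greenhouse
    climate generator for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
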