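Package: milkintake
Title: Probabilistic Estimation of Breast-Milk Caloric Intake in Infancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo model of the caloric intake that breastfed infants
    aged 0-24 months obtain from breast milk, per feeding and per day,
    expressed per kilogram of body weight. Feeding frequency, volume per
    feed, milk caloric density and infant weight are described by
    triangular, Beta-PERT, normal and uniform distributions stratified into
    seven age groups; caloric-density inputs can be derived from
    study-level evidence by DerSimonian-Laird random-effects pooling with
    Cochran's Q, Tau-squared and I-squared heterogeneity diagnostics.
    Simulated intake distributions are summarised into low, medium and high
    intake scenarios defined by their quartiles, with convergence
    monitoring and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
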