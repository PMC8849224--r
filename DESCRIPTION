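Package: caffpx
Title: Simulation and Non-Compartmental Analysis of Daily Caffeine and
    Paraxanthine Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying salivary caffeine and paraxanthine kinetics
    under a conventional pattern of daily caffeine intake (150 mg three times
    a day for ten days). Provides a seeded cohort simulator built on
    closed-form first-order absorption/elimination kinetics with
    parent-to-metabolite conversion and multiple-dose superposition, the
    non-compartmental descriptors used in saliva studies (peak level and
    time, C50 half-life, log-linear elimination rate, trapezoidal AUC,
    overnight residual, metabolite disproportionality), inter-individual
    association statistics with Benjamini-Hochberg false-discovery control,
    pointwise paired condition contrasts, and a reproducible CSV pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
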