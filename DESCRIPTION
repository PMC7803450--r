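Package: htnce
Title: Cost-Utility Markov Modelling of Antihypertensive Treatment by Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort cost-utility model for deciding the 10-year
    cardiovascular disease (CVD) risk level at which starting antihypertensive
    drug treatment in stage 1 hypertension is cost-effective. Provides a 15-state
    cohort engine with one-year cycles, half-cycle correction and discounting;
    calibration of annual first-event probabilities to a 10-year risk with an
    additive age increment; standardized-mortality-ratio post-event mortality;
    incremental cost-effectiveness (ICER, net monetary benefit, dominance) and
    number-needed-to-treat; probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves; and bisection search for the risk
    threshold at which treatment becomes cost-effective. Parameter bundles load
    from a YAML configuration plus CSV tables, and a synthetic base-case
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
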