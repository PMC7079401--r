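Package: stressproc
Title: Stress-Process Structural Equation Modelling for Antenatal Depression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing community screening cohorts of pregnant women
    under Pearlin's stress-process framework. Scores and classifies the
    Edinburgh Postnatal Depression Scale (EPDS), the Oslo Social Support Scale
    (OSSS-3), a four-item perinatal coping inventory and mid-upper-arm
    circumference; runs contingency-table screening with an exact-test
    fallback rule and exact binomial prevalence intervals; selects predictors
    with random-intercept mixed models over sampling clusters; parcels EPDS
    items for the measurement model; and fits recursive structural equation
    models by normal-theory maximum likelihood with Satorra-Bentler robust
    chi-square, standard fit indices, standardized solutions and
    direct/indirect/total effect decomposition with delta-method standard
    errors. A calibrated synthetic-cohort generator reproduces the marginal
    and path structure such cohorts exhibit, so every stage of the pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
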