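Package: naqcat
Title: Rasch Rating Scale Measurement and Computerized Adaptive Testing
    for the Negative Acts Questionnaire-Revised
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring exposure to workplace bullying with the
    22-item Negative Acts Questionnaire-Revised (NAQ-R) under the Andrich
    rating scale model. Provides closed-form category probabilities,
    information and test characteristic curves; joint maximum-likelihood
    calibration of item difficulties and shared category thresholds with
    infit/outfit fit statistics, point-measure correlations, separation
    reliability and differential item functioning screening; a
    unidimensionality workflow (Horn's parallel analysis, principal
    components analysis of standardized Rasch residuals, and Smith's
    person-level subset t tests); a computerized adaptive testing engine
    with maximum-information item selection, Newton-Raphson provisional
    estimation and standard-error stopping rules; adaptive-versus-full-test
    efficiency and precision comparison; ROC-based cutoff determination
    with individual victimization probabilities; and a synthetic response
    generator built on the published NAQ-R item bank.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
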