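Package: rtmbias
Title: Monte Carlo Study of Selective Attrition and Regression-to-the-Mean
    Bias in Prediction-of-Change Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal pre/post samples from linear-Gaussian
    structural population models in which the baseline association between a
    health measure and a predictor is driven by latent causes with either
    transient or enduring effects, induces selective attrition by listwise
    deletion of the subjects with the highest latent liability of dropping
    out, and fits baseline-adjusted multiple regression and change-score
    analyses to the retained subjects. Replicate-level fits are aggregated
    into mean coefficients, mean standard errors, 95% confidence-interval
    coverage and mean change scores, quantifying how selective attrition and
    inappropriate modeling of regression toward the mean bias estimates of
    the prediction of change. Closed-form truncated-Gaussian estimands are
    provided as an analytic oracle for every simulated cell.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
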