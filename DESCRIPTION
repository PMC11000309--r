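Package: respseg
Title: Responder Segmentation via Cross-Validation-Optimised Probability Cutoffs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-driven segmentation of clinical-trial patients into
    responders and non-responders. Searches seven families of
    cross-validation techniques for the configuration whose out-of-fold
    logistic-regression probabilities yield the largest F1-optimal
    probability cutoff, pools coefficients and cutoffs across two training
    trials into a linear scoring system, segments test patients against the
    pooled cutoff, and evaluates segmentation quality with classification
    metrics and survival models (Kaplan-Meier, log-rank, Cox proportional
    hazards, accelerated failure time, AIC). Includes a synthetic trial
    generator emulating baseline covariates, longitudinal tumor-size
    trajectories, best-overall-response labels and right-censored overall
    survival, so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
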