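Package: ccts
Title: Continual Training of Time-Aware Recurrent Classifiers on Evolving
    Clinical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous classification of irregularly sampled
    multivariate time series whose label is fixed at the final time, treating
    each growing prefix length as a distinct data distribution. Implements a
    time-aware LSTM with elapsed-time memory discounting, a restricted-update
    training strategy combining a Fisher-information importance penalty
    (limitation mechanism) with a projection-free recursive-gradient update
    (promotion mechanism), continual-learning metrics (backward and forward
    transfer, gradient fluctuation, AUC with confidence interval,
    Bonferroni-Dunn critical differences), importance-based model
    interpretation with Bayesian online changepoint staging and biomarker
    ranking, and a synthetic generator of multi-stage labeled time series for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
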