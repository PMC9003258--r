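Package: crwave
Title: Compensatory Reserve Estimation from Arterial Waveforms Under
    Simulated Central Hypovolemia
Version: 0.1.0
Authors@R:
    person("crwave", "maintainers", email = "crwave@example.org",
           role = c("aut", "cre"))
Description: Simulates staged lower-body negative pressure (LBNP)
    hemorrhage-tolerance experiments as finger arterial pressure
    waveforms, implements two machine-learning estimators of the
    compensatory reserve (a 1-D convolutional network on normalized
    20-second waveform segments, and a per-beat morphology-feature
    regression averaged over a 30-beat sliding window), and compares
    them head to head with clustered logistic regression, ROC AUC with
    DeLong inference, per-stage least-squares means, end-of-stage
    regression, and dependent-correlation (Steiger) tests, stratified
    by tolerance to central hypovolemia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
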