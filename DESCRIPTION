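Package: rehabstack
Title: Hybrid Incremental Learning for Home-Based Mobility-Test Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for individualised home-based rehabilitation support built on
    the Timed Up and Go (TUG) and Five Time Sit To Stand (FTSTS) mobility tests.
    Generates synthetic patient cohorts from published per-class summary
    statistics via sorted Gaussian sampling with controlled variability swaps,
    prepares data (BMI derivation, 3-sigma outlier removal, [-1,1]
    normalisation, SMOTE class balancing), fits a hybrid classifier pairing
    gradient-boosted trees with k-nearest neighbours, selects predictions by
    improvement-rate-gated distance to the healthy cluster, retrains
    incrementally per user, raises clinical state flags, and evaluates with
    confusion-matrix metrics and cumulative accuracy curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
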