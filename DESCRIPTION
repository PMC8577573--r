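Package: rfsv
Title: Personalized Blood-Pressure Modeling from Wearables with
    Shapley-Value Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject models of home blood pressure from
    minute-level wearable streams (heart rate, steps, speed, floors),
    sleep sessions and twice-daily blood-pressure logs.  Implements
    lifestyle feature engineering over 1/24/48/72-hour windows with
    heart-rate-zone activity levels, seasonal ARIMA one-step-forecast
    features from irregularly sampled blood-pressure series, random-forest
    regression with Shapley-value-based feature selection (RFSV),
    model comparison against mean/ARIMA baselines with repeated
    cross-validation and paired t-tests, and generation of top-3
    actionable lifestyle recommendations.  Includes a synthetic
    wearable-data simulator with planted, known lifestyle effects so the
    whole pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
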