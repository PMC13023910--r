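Package: mectox
Title: Machine-Learning Quantification of Toxicant Mixtures from
    Microbial Electrochemical Sensor Current Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual toxicants in multi-component
    mixtures from the chronoamperometric current-time response of microbial
    electrochemical cell (MEC) biosensors. Enumerates full mixture exposure
    designs (combinations, volume ratios, equivalent-concentration gradients),
    simulates toxicokinetically structured current traces with stored ground
    truth, extracts a 22-indicator feature set from each trace, computes
    mixture-interaction statistics (Interaction Index, fixed-time linear
    calibrations), trains and compares SVM, KNN, PLS and random-forest
    concentration regressors under ten-fold cross-validation, and runs an
    overfitting-diagnostics suite (learning curves, grouped train/test splits,
    out-of-bag agreement, Gini feature importance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
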