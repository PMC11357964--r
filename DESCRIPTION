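Package: milcalib
Title: Calibration-Aware Multi-Instance Learning for Treatment-Failure Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-patient risk of targeted-therapy failure from
    routine clinical features by training a one-hidden-layer multi-instance
    neural network whose loss is derived from the Hosmer-Lemeshow
    goodness-of-fit statistic, so that the fitted risks are statistically
    calibrated by construction. Patients are min-max normalised, clustered
    with k-means, and resampled with replacement into bags whose label is the
    mean min-max-scaled progression-free survival of their members; the bag
    prediction is the maximum instance output. After training, an optimal
    mutation-abundance threshold is searched that maximises the between-group
    difference in mean predicted failure risk, and the resulting high/low-risk
    strata are compared by Welch's t-test and Kaplan-Meier/log-rank analysis.
    Includes a seeded synthetic-cohort generator for end-to-end testing,
    four classical regression baseline losses (MSE, MAE, Huber, log-cosh),
    and ggplot2 visualisations of training, calibration and survival.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
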