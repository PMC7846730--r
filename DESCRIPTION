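Package: threadmotion
Title: Head-Motion Classification from Thread-Based Strain Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Signal-processing and classification pipeline for two-channel
    impedance recordings from crossed strain-sensing threads worn on the back
    of the neck. Provides a synthetic-signal generator that emulates the
    per-orientation signal structure of the sensor pair, calibration of
    per-channel baseline and range, moving-average filtering, piecewise
    asymmetric normalization, overlapping-window segmentation, six-feature
    extraction (per-channel means, mean difference, Pearson correlation,
    per-channel min-max range), nine classifier configurations (linear,
    quadratic, cubic and Gaussian-kernel SVM; Gaussian and kernel naive
    Bayes; cosine, cubic and distance-weighted KNN), and repeated random
    holdout evaluation with pooled confusion matrices for classifying head
    orientation into nine positions along the horizontal and vertical axes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
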