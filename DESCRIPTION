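Package: fmodal
Title: Functional L1-Modal Regression with Data-Driven Bandwidth Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric prediction of a scalar response from a functional
    covariate (a curve observed on a common grid) via the conditional mode.
    The mode is estimated robustly through the derivative of a kernel-weighted
    check-loss conditional quantile rather than through a conditional density,
    which makes the predictor resistant to outliers and heavy-tailed errors.
    Includes L2 and functional-PCA semi-metrics between curves, local
    (k-nearest-neighbour) and global (distance-quantile) candidate bandwidth
    grids with leave-one-curve-out cross-validation selectors under
    squared-error or absolute-error loss, comparison estimators (kernel
    L1-median and a density-based kernel mode), a heteroscedastic two-regime
    curve simulator with signal-to-noise calibration, and a contamination
    harness for robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
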