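Package: esnclass
Title: Echo State Network Classifiers for Regular and Irregular Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Backpropagation-free time series classification with fixed random
    leaky-integrator reservoirs. Implements a differential echo state network
    for equal-length regular series (adjacent-difference input encoding,
    per-neuron variance hallmarks, linear support vector readout) and an
    interpolation echo state network for irregular longitudinal cohorts such
    as cancer-screening biomarker series (monthly linear interpolation,
    skip-sampled reservoir states, calibrated probability readout and
    months-ahead forecasting). Ships seed-deterministic synthetic data
    generators for both data shapes and the matching evaluation protocols:
    seed robustness, test-set noise robustness, repeated random 50-50 splits
    with ROC AUC, and a last-timepoint logistic regression baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
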