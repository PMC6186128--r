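Package: bclr
Title: Bootstrap-Aggregated Gene Co-Expression Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers gene co-expression networks with the context likelihood
    of relatedness (CLR) algorithm, using a B-spline mutual information
    estimator, or with Pearson correlation, and stabilises them by
    condition-level bootstrap aggregation (random subspace resampling with
    edge-weight averaging, "BCLR"). Provides masked precision-recall
    evaluation against partial directed regulator-target standards, network
    stability assessment by mean absolute error to a parent network,
    functional edge overlap, condition-removal and subsampling-fraction
    experiment harnesses with stability-based fraction selection, and a
    linear-Gaussian synthetic compendium generator emulating the layout of
    perturbation compendia such as the DREAM5 files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
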