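Package: cocs
Title: Coherent Complex-Spike Analysis for Cerebellar Purkinje Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Purkinje cell population activity recorded
    during a multisensory go/no-go licking task. Provides a synthetic session
    generator with known ground truth (dendritic calcium event rasters,
    fluorescence traces, trial tables, and paired simple/complex spike
    trains), rolling-percentile delta-F/F normalisation and exponential-kernel
    complex-spike event detection, discovery of parasagittal zones by
    sequential binary k-means on trace correlation matrices, extraction of
    coherent complex-spike (CoCS) events and their trial-aligned coherence
    statistics, millisecond spike synchrony with a per-trial permutation null
    and shift-predictor-corrected JPSTH, signal-detection behavioural metrics
    (d-prime, lick latency residuals), and normal-family regression models
    (OLS with leave-one-out likelihood-ratio tests and a maximum-likelihood
    linear mixed model with a per-mouse random intercept).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    withr
Config/testthat/edition: 3
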