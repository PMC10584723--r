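Package: serialdep
Title: Serial Dependence Analysis for Continuous-Report Face Adjustment Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing serial dependence in continuous-report
    (adjust-to-match) experiments on a circular morph continuum of face
    images. Provides the circular stimulus-space geometry (signed shortest
    distances, prototype categories), trial derivation and lapse filtering,
    constrained multi-start least-squares fitting of the derivative-of-
    Gaussian bias curve with half-amplitude estimation, trial-level
    bootstrap confidence intervals (percentile and BCa), a nonparametric
    categorical classification-error index, a generative observer model
    with known ground-truth bias for parameter-recovery studies, and an
    orchestration layer reproducing the full per-condition analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
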