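Package: impulsewm
Title: Impulse-Response Decoding of Visual Working Memory from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing "activity-silent" visual working memory with a
    task-irrelevant impulse stimulus. Implements trial-wise Mahalanobis
    distance-difference decoding of remembered orientation from multichannel
    EEG epochs (leave-one-trial-out, shrinkage-regularized pooled error
    covariance), cross-temporal and cross-epoch generalization, shifted
    training and lag-correlation latency analyses, cluster-based
    sign-permutation inference, a two-parameter 2AFC mixture model of
    memory performance, and a synthetic epoch generator that reproduces the
    trial and signal structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
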