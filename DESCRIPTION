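Package: grimscan
Title: Automated Screening of Post-Anesthetic Effects from Mouse Facial Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for recognizing post-anesthetic and post-surgical effects
    in images of black-furred laboratory mice. Provides a seedable synthetic
    face-image generator with ground-truth geometry and latent grimace-scale
    action units, two-stage cascade face detection with geometric part
    heuristics, binary label assignment from treatment and acquisition time,
    subject-disjoint cross-validation, a small convolutional network trained
    from scratch (plus a frozen-backbone softmax-head path), confusion-based
    evaluation with per-animal confidence averaging, cross-treatment transfer
    matrices, and deep Taylor decomposition relevance heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
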