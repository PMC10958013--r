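Package: numerosense
Title: Emergent Number Sense from Action-Prediction Pretraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates put/take/shake object-manipulation image sequences,
    trains a Siamese convolutional network solely on predicting which
    manipulation occurred between two views of a scene (at most three
    objects during training), and analyses the learned image embedding for
    emergent numerical structure: unsupervised number categories found by
    density-based clustering, a subitization limit, an ordered embedding
    line calibrated by the zero-to-one cluster distance, and relative
    (two-alternative forced choice) and absolute numerosity estimation for
    scenes with up to thirty objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
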