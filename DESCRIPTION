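Package: fsdacam
Title: Foley-Sammon Discriminant Reduction, Clinical-Variable Fusion and
    Projection-Aware Class Activation Maps
Version: 0.1.0
Authors@R:
    person("Rachel", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binary medical-image classification from frozen deep-network
    features in the small-sample regime (M features comparable to or larger
    than N samples). Implements the recursive Foley-Sammon procedure that
    extracts an ordered set of orthonormal discriminant directions maximizing
    the Fisher criterion beyond the rank-one limit of classical binary LDA,
    projects high-dimensional backbone features onto the resulting subspace,
    fuses the reduced features with encoded or embedded clinical variables by
    concatenation, trains margin or linear classifiers under stratified
    cross-validation, and renders class activation maps by back-projecting
    linear-classifier weights through the discriminant projection onto the
    last convolutional feature map. A synthetic-data module generates
    class-conditional Gaussian features, label-correlated clinical tables and
    planted-blob feature maps so the whole pipeline is testable without
    external imaging datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
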