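Package: earcount
Title: Automatic Wheat Ear Counting from Zenithal RGB Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic image-processing pipeline for counting wheat ears
    in zenithal RGB photographs of crop canopies: a frequency-domain
    Laplacian high-pass enhancement, a large-window median rank filter, and
    prominence-based local-maxima segmentation followed by particle
    counting.  Includes conversion of per-image counts to ears per square
    meter from pinhole camera geometry, count-validation statistics
    (success rate, Pearson correlation, linear regression), greyscale and
    block-average resolution-degradation simulations with proportional
    median-window rescaling, and a seeded synthetic canopy-scene generator
    with exact ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
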