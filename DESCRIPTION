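Package: liverseg
Title: Automatic Liver Segmentation by Auto-Context Texture
    Classification and Prior-Guided Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments the liver in 2D CT slices without user interaction.
    Gray-level co-occurrence matrix (GLCM) texture descriptors feed a
    cascade of AdaBoost pixel classifiers in which each stage augments the
    appearance features with probabilities sampled along eight rays from
    the previous stage's output map (auto-context).  The resulting prior
    probability map supplies automatic seeds and an extra edge-weight term
    for a random-walker graph segmentation.  Includes volumetric overlap
    and surface-distance evaluation metrics with the associated challenge
    scoring, and a synthetic abdominal-phantom generator so that training,
    segmentation and evaluation can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    Matrix,
    png,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
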