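Package: netrank
Title: Network-Based Gene Prioritisation by Damped Score Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks genes as candidate biomarkers by fusing each gene's
    statistical association with a binary phenotype and its connectivity in
    a weighted gene network, using a damped, degree-normalised random-surfer
    iteration (the NetRank algorithm). Includes expression-matrix cleaning
    and min-max normalisation, stratified development/test splitting,
    point-biserial correlation priors, STRING-style edge-list import,
    soft-thresholded co-expression network construction with scale-free
    topology fitting, top-K signature selection under a p-value cutoff,
    held-out evaluation by principal-component AUC and support vector
    machines, and a seeded synthetic-data generator with planted biomarker
    modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    pROC,
    jsonlite,
    withr,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
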