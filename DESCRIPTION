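Package: hyperptm
Title: Predicting Directed Phosphorylation and Dephosphorylation
    Interactions from Hyperbolic Network Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds a protein-protein interaction network in the
    two-dimensional hyperbolic plane (LaBNE angular initialisation refined by
    HyperMap-style likelihood maximisation under the popularity-similarity
    model), clusters proteins along the angular (similarity) dimension by
    gap cutting, assembles fourteen geometric and centrality features per
    directed protein pair, trains a random forest with under-sampled
    repeated cross-validation to recognise directed post-translational
    modification interactions (effector to target), and scores every
    network edge in both directions. Includes a popularity-similarity
    network generator with ground-truth coordinates and planted effector
    annotations, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
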