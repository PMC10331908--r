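Package: beaknest
Title: Beak Morphology and Avian Nest-Material Use with Phylogenetic Bias Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking avian beak morphology and ecology to nest-material
    use at the species level. Codes free-text nest-material descriptors into seven
    categories (binder, fibre, grass, leaf, mineral, silk, twig) and resolves each
    species' primary material and specialist status; fits random-forest classifiers
    (binary per-material, primary-material, specialist-only) with out-of-bag accuracy
    reporting and predictor-contribution decomposition; quantifies two biases of such
    models with a Brownian-motion/Mk phylogenetic-simulation null and a class-balanced
    downsampling null; and provides a confirmatory phylogenetic logistic-regression
    track (beak-morphospace PCA, estimating-equation fits with an OU-type attraction
    parameter, AIC model selection). A synthetic-data generator produces trees,
    morpho-ecological predictors and material labels with tunable phylogenetic signal
    so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    randomForest,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    yaml,
    withr
Config/testthat/edition: 3
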