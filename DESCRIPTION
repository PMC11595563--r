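Package: phylospat
Title: Spatiotemporal Pattern Analysis from Ensemble Distribution Models
    and Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the spatiotemporal pattern of a taxon from
    georeferenced occurrence records, environmental raster layers and a
    time-calibrated phylogeny. Implements spatial thinning of occurrences,
    Pearson collinearity filtering of environmental variables, ensemble
    species distribution modelling (GLM, GAM, gradient boosting and random
    forest members combined by committee averaging and AUC-weighted mean),
    exact Fisher-Jenks natural-breaks classification of habitat
    suitability, Mk-model ancestral area reconstruction via Felsenstein
    pruning (ER, SYM and ARD parameterisations), stem-age extraction and
    per-grid-cell mean divergence times, and nonparametric comparison of
    divergence times across suitability classes with Dunn-Holm post hoc
    tests. A synthetic-data generator produces spatially autocorrelated
    raster stacks, presences from a known suitability surface, Yule
    chronograms and Mk-evolved tip areas so the whole pipeline is testable
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    mgcv,
    randomForest,
    xgboost,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
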