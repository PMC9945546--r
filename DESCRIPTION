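Package: disjunctSDM
Title: Niche Differentiation and Climate-Change Range Dynamics for
    Species with Disjunct Population Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing climatic-niche differentiation between
    geographically disjunct population groups of a species and for projecting
    range change under future climate scenarios. Implements gridded
    environmental-space niche densities with Schoener's D overlap and the
    background-randomization niche similarity test; presence-background
    species distribution models with pseudo-absence sampling and repeated
    split-sample cross-validation for whole-species, core-group and
    disjunct-group data sets; ROC-based evaluation (AUC, TSS, sensitivity)
    with three binarization threshold rules; aggregate (union) models,
    majority-consensus ensembles, and a range-change index. Includes a
    synthetic-data module generating spatially autocorrelated climate
    landscapes, future scenarios, and virtual species with known-truth niches
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmnet,
    pROC
Config/testthat/edition: 3
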