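Package: endemicshift
Title: Ensemble Niche-Model Projections of Climate-Change Impacts on Endemic Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic pipeline for projecting climate-change
    impacts on endemic species with ensemble species distribution models (SDMs).
    Generates spatially autocorrelated bioclim-like climate grids, country and
    ecoregion masks, and virtual species with known Gaussian niches; applies
    occurrence filtering and collinearity-based predictor selection; fits a
    multi-algorithm presence/pseudo-absence ensemble with AUC-weighted consensus
    and TSS-threshold binarization; and computes the downstream biodiversity
    metrics (range change, stacked richness, delta-SR, potential species
    hotspots, temporal Sorensen dissimilarity, climate profiles) used to
    contrast a control warming scenario against a more climatically dissimilar
    "melting" scenario family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
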