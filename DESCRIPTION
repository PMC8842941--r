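Package: LTSquant
Title: Quantification of Lewy-Type Synucleinopathy in Stained Whole-Slide
    Images
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying Lewy-type synucleinopathy
    (LTS) in immunohistochemically stained submandibular-gland whole-slide
    images. Provides a synthetic slide and cohort generator with exact ground
    truth, confidence-ranked annotation handling with inter-rater concordance
    statistics (Fleiss' kappa, pairwise agreement), weighted-loss patch
    classification with strided sliding-window inference, H-DAB colour
    deconvolution and stain statistics, affinity-propagation clustering with
    six cluster validity indices, spatial object-graph and point-pattern
    homogeneity features, and repeated-LASSO feature selection with
    elastic-net logistic prediction of disease status and stage, plus the
    rank-based cohort statistics used to evaluate such models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    nnet,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, Classification, Clustering, FeatureExtraction,
    Pathology, Spatial
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
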