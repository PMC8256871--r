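Package: phenogrowth
Title: Image-Based Growth Rate, Water-Use Index and Heritability Analysis for Pot Phenotyping Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for high-throughput pot phenotyping of plants under
    contrasting soil-moisture regimes. Segments plants from top and side view
    images and extracts geometric and near-infrared features, compares eight
    multivariate regression families (linear, stepwise, principal-component,
    partial least squares, elastic net, random forest, gradient boosting and
    multivariate adaptive regression splines) under repeated cross-validation
    to predict fresh shoot biomass, derives smoothing-spline absolute and
    relative growth rates, converts pot weighing records into daily water use
    and water-use indices, and estimates broad-sense heritability of derived
    traits by the standard, Cullis and Piepho estimators, with Duncan multiple
    range tests for genotype comparisons. Includes a synthetic experiment
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Matrix,
    lme4,
    glmnet,
    randomForest,
    xgboost,
    car,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
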