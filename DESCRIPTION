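Package: ecvnet
Title: Edge Contribution Value Analysis of Gene Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Differential gene-network analysis for small-sample bulk
    RNA-Seq. Normalizes a gene-by-sample count matrix to transcripts per
    million (TPM), estimates a directed gene expression network by
    score-based search over additive spline regressions, scores every
    edge in every sample with an edge contribution value (ECv), ranks
    edges by the between-group difference in average ECv to extract
    differentially regulated edges and their subnetworks, and evaluates
    candidate marker genes by AUC, optimal cutoffs, classification
    trees, stepwise-AIC logistic regression and leave-one-out
    cross-validation. A synthetic-data generator produces counts from a
    known true network with known perturbed edges so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    randomForest,
    splines,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
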