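Package: saltgrad
Title: Salinity-Gradient Diversity and Co-Occurrence Network Analysis for
    Soil Microbiomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bacterial and archaeal communities along
    natural salinity stress gradients: rarefaction and compositional
    transforms of ASV tables, alpha/beta diversity statistics with
    permutation tests, sparse inverse-covariance co-occurrence network
    inference with StARS stability selection, assembly-process
    classification of network links, community cohesion and
    natural-connectivity fragility metrics, stress-threshold (segmented)
    gradient models, and a random-forest / mixed-model / piecewise
    structural-equation-model driver cascade. Includes a synthetic
    community generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    glmnet,
    vegan,
    mgcv,
    lme4,
    car,
    randomForest,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
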