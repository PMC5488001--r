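Package: metabobench
Title: Simulation-Based Benchmarking of Classifiers for Untargeted
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates untargeted metabolomics abundance data with
    block-wise correlation structure drawn from random C-vine correlation
    matrices, hierarchical phenotype effects, skewed (generalized
    Gaussian) marginals, biological and technical outliers, unbalanced
    phenotype allocation, and limit-of-detection (missing not at random)
    missingness. Benchmarks seven multiclass classifiers (PLS-DA and
    sparse PLS-DA via NIPALS, support vector machines, Random Forests,
    feedforward neural networks trained by resilient backpropagation,
    naive Bayes, and k-nearest neighbours) with cross-validated grid
    tuning, kernel smoothing of the loss surface, significance
    filtering, and both misclassification-rate and cross-entropy loss,
    over repeated simulation studies or user-supplied abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mixOmics
Config/testthat/edition: 3
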