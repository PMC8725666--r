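Package: costlearn
Title: Cost-Sensitive Learning and Feature Selection for High-Dimensional
    Imbalanced Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid learning strategies for two-class datasets that are both
    high-dimensional and class-imbalanced, as commonly found in gene-expression
    studies. Provides six instance-weightable feature-ranking heuristics
    (Pearson correlation, information gain, gain ratio, ReliefF, linear-SVM
    attribute weighting, and SVM recursive feature elimination), a
    cost-sensitive meta-learning layer (instance reweighting from a
    misclassification cost matrix and minimum-expected-cost probability
    thresholding), a 100-tree random-forest base learner, imbalance-aware
    evaluation metrics (MCC, G-mean, F-measure), a repeated stratified
    cross-validation harness with Wilcoxon signed-rank and Holm-Bonferroni
    comparisons, an ARFF reader/writer, and a generator of synthetic
    imbalanced expression-like benchmarks with known informative features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    foreign,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
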