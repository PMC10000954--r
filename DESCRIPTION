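Package: aoahg
Title: Hybrid Arithmetic Optimization and Hunger Games Search for Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional embeddings (for
    example deep-CNN image descriptors) using a hybrid metaheuristic that
    gates arithmetic optimization algorithm (AOA) operators with hunger
    games search (HGS) operators. Provides the hybrid AOAHG driver together
    with plain AOA and HGS baselines, a classifier-based fitness (SVM,
    k-nearest neighbours, random forest, gradient-boosted trees), an
    exhaustive subset-enumeration oracle for small problems, a synthetic
    embedding generator with a planted informative-feature subset, and a
    benchmark harness that crosses optimizers with classifier back-ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    class,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
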