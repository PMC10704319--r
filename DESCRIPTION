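Package: hivstkey
Title: Key Influencer Identification for Secondary Distribution of HIV
    Self-Testing Kits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies key influencers for secondary distribution of HIV
    self-testing (HIVST) kits among men who have sex with men. Implements an
    ensemble classification system that combines logistic regression, a
    linear support vector machine, a classification tree and a random forest
    through soft voting, selects predictors by cross-model importance voting
    (standardized coefficients, recursive feature elimination and Gini
    impurity), and benchmarks it against a six-item self-reported leadership
    scale with rank-order cutoffs. Includes a calibrated synthetic trial-data
    generator, stratified cross-validated evaluation with
    increased-percentage statistics and Wald difference-of-proportions
    confidence intervals, and a Poisson kit-diffusion simulator on the
    bipartite index-alter network to compare intervention efficiency of
    seeding strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
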