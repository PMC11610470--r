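Package: retroniche
Title: Retrospective Evaluation of Ecological Niche Model Transferability
    Across Time Periods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrospective cross-temporal framework for evaluating how well
    ecological niche models transfer between two climate periods. Provides a
    native Bioclim climatic-envelope implementation and a uniform fit/project
    interface over six further algorithms (GLM, GAM, boosted regression trees,
    a Maxent-style penalized logistic, random forest, support vector machine),
    the auto/cross model quadruple with a 70 percent map-similarity control
    gate, pixel-wise transfer metrics (True Skill Statistic, Overlap Index and
    the two printed error rates), exact binomial model validation,
    Mobility-Oriented Parity (MOP) analysis of strict-extrapolation areas,
    nonparametric algorithm-comparison statistics with a Nemenyi post hoc
    test, and a virtual-world simulator (paired-period synthetic climates and
    virtual species with known niches) so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    e1071,
    xgboost,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
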