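Package: digimood
Title: Multimodal Digital Phenotyping of Depression from Actigraphy and
    App-Based Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for digital phenotyping of major depressive disorder
    from one week of multimodal monitoring: minute-epoch wrist actigraphy
    (rest-activity, sleep estimation, cosinor and nonparametric circadian
    rhythm analysis) and app-derived streams (facial action-unit presence,
    prosodic speech timing, word-category usage, and mood diaries).
    Includes a synthetic-cohort generator that emulates the group effect
    structure of case-control depression studies, a normality-driven
    group-comparison layer with Bonferroni post hoc tests and covariate-
    adjusted regression, optimal cutpoint search for one-dimensional
    markers, and leave-one-out cross-validated multimodal classification
    with seven standard supervised learners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    class,
    e1071,
    nnet,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
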