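Package: fsspipe
Title: Feature-Set-Guided Evolutionary Search for Machine Learning Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated search over linear machine-learning pipelines by
    strongly typed genetic programming.  A Feature Set Selector first stage
    restricts the data to one pre-defined group of features (such as a gene
    co-expression module), user templates constrain pipeline shape, and
    NSGA-II selection trades cross-validated accuracy against pipeline
    complexity, with a percentile rule guarding the final choice against
    overfitting.  Includes an interaction-effect expression-data simulator
    with module structure and a replicate benchmark harness with Welch
    one-sided tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
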