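Package: mushroomsim
Title: Creation, Curation and Simulation of Attribute-Based Mushroom Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building species-level mushroom trait tables from
    field-guide text, curating them against the classic 1987 attribute
    format, simulating hypothetical mushroom entries with correlated
    quantitative traits via a Cholesky factor, running data-quality checks
    (class balance, missingness filtering, most-frequent imputation, a
    mixed-type pairwise association matrix based on Theil's U, Pearson
    correlation and the correlation ratio), and evaluating binary edibility
    classifiers with cross-validated accuracy, precision, recall, F-beta and
    ROC/AUC metrics. A deterministic fixture generator emits synthetic
    field-guide documents and primary tables so the whole pipeline can be
    exercised without any copyrighted source text.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    xml2,
    yaml,
    ggplot2,
    generics,
    MASS,
    e1071,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
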