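Package: gxebag
Title: Gene-Environment Interaction Testing via Bagged Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for gene-environment (GxE) interactions that
    construct an internal genetic risk score (GRS) by bootstrap aggregating
    (bagging) and use out-of-bag predictions so that the full sample serves
    both GRS construction and interaction testing. Provides the bagged
    elastic-net test, the random-forest test, and reference procedures
    (single-SNP Bonferroni test, split-sample GRS test, SBERIA), together
    with synthetic-data generators and a Monte-Carlo experiment runner for
    type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
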