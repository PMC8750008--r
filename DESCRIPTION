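Package: lmmasca
Title: Linear Mixed Model ASCA for Nested Factorial Quality-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-variable linear mixed models with a single grouping-unit
    random intercept over a nested factorial sampling design, assesses factor
    significance by restricted (nesting-preserving) permutation of the
    observation-expanded sums of squares, and summarises the per-factor effect
    matrices by simultaneous component analysis (ASCA): singular value
    decomposition of the centered level-by-variable effect matrices, explained
    variance, variable contributions, biplot data, and k-means clustering of
    factor-level scores with silhouette-based model selection. Includes a
    synthetic-data generator emulating a two-year bi-monthly cheese-wheel
    sampling campaign (15 dairies, 317 wheels, 6 sampling positions per wheel)
    so the whole pipeline is testable without confidential production data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
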