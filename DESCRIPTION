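Package: zoomorph
Title: Morphostructural Characterization of Local Goat Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the zoometric (morphostructural) characterization of
    local livestock populations from linear body measurements, developed around
    the Black Creole goat of central Mexico. Provides validated reading and
    writing of per-animal measurement tables, a proportion-precision sample-size
    calculator, descriptive statistics with coefficient-of-variation homogeneity
    screening, nine classical zoometric indices with zootechnical classification,
    a Spearman-correlation morphological-harmony model, correlation-matrix
    principal component analysis with Kaiser retention and communalities, and
    Ward hierarchical clustering of locality mean profiles on standardized
    Euclidean distances. A seeded synthetic-herd generator reproduces the
    published moment, range and rank-correlation structure of the study
    population so that every stage of the pipeline is testable without the
    original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
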