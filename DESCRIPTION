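Package: floatdoe
Title: Dissolution Similarity, Bootstrap f2 Intervals and DoE Tools for
    Floating Tablet Formulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Statistical workflow for optimizing sustained-release floating
    matrix tablets from in vitro dissolution data. Implements the
    Moore-Flanner similarity factor f2 and its variance-penalized unbiased
    estimate E(f2), nonparametric bootstrap percentile and bias-corrected
    accelerated (BCa) 90 percent intervals with the associated equivalence
    decision rule, release-kinetics model fitting (zero-order, first-order,
    Higuchi, Korsmeyer-Peppas) with mechanism classification, two-level full
    factorial and face-centered central composite response-surface designs
    with coded/actual ordinary-least-squares models, RMSEP external
    validation, an HPMC threshold solver, tablet mass-balance accounting,
    swelling and matrix-erosion statistics, and a synthetic dissolution data
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
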