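Package: paleodiv
Title: Hill-Number Diversity of Paradigmatically Classified Artifact Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of class diversity in archaeological
    artifact assemblages, built around Early Paleoindian fluted projectile
    points. Provides a paradigmatic morphometric classification (seven
    quantitative characters intersected into classes), Hill-number diversity
    of orders 0, 1 and 2 with nonparametric asymptotic estimators (Chao1,
    low-bias Shannon entropy, unbiased Simpson), improved Good-Turing sample
    coverage, seamless size- and coverage-based rarefaction and extrapolation
    curves, bootstrap confidence intervals, a coverage-driven estimator of the
    coefficient of variation of class abundances, and Sorensen-weighted
    class-sharing networks between assemblages. Includes a synthetic-data
    generator with known ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
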