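Package: procopt
Title: Multi-Criteria Weighting and Design-of-Experiments Optimization for
    Formulation Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-stage optimization workflow used in
    pharmaceutical formulation development: combined subjective-objective
    criterion weighting (analytic hierarchy process with entropy weighting),
    min-max standardization and comprehensive scoring of orthogonal-array
    extraction experiments with range analysis and ANOVA, Box-Behnken
    response-surface designs with full quadratic fits, lack-of-fit ANOVA and
    constrained optimization over the coded cube, and replicate-set relative
    standard deviation statistics for analytical method validation. Includes
    seed-deterministic synthetic-data generators for every stage and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
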