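Package: bambaraSI
Title: Phenotypic Selection Indices and Heritability Analysis for Bambara Groundnut Pre-Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pre-breeding analysis of bambara groundnut (Vigna
    subterranea) trait data: derived seed-composition and yield traits
    (carbohydrate by difference, nitrogen-to-protein conversion, fresh-to-dry
    conversion, single seed size, shelling percentage, metabolizable-energy
    partitioning), broad-sense heritability by parent-offspring regression and
    by genotype-by-environment variance components (expected-mean-squares and
    EM-REML estimators), trait correlation and principal-component statistics
    with significance thresholds, and a base linear phenotypic selection-index
    engine (standard-normal-deviate scoring, weighted scenario registry,
    independent culling levels, expected genetic gain). A seeded synthetic-data
    generator emulates correlated line-by-trait matrices, replicated
    genotype-by-environment trials, and multi-generation parent-offspring data
    with known heritability.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
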