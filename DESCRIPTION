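Package: trioscope
Title: Family-Based Decomposition of Common and Rare Genetic Contributions to a Binary Proband Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proband-parent trio studies of a binary phenotype:
    Mendelian inheritance classification of rare coding variants and copy
    number variants (de novo, transmitted, non-transmitted), damaging-variant
    prioritisation with CADD and MPC scores, ultra-rare filtering against a
    parental cohort and an external reference, LD clumping and thresholded
    polygenic scoring with pseudo-control (non-transmitted) scores and the
    polygenic transmission disequilibrium test, Firth penalized logistic
    regression and companion exact statistics, a liability-threshold power
    simulation, and a synthetic trio-cohort generator so the full pipeline is
    testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
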