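Package: ssgblup
Title: Single-Step Genomic Evaluations and Indirect Prediction of
    Genotyped Selection Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unified single-step genomic best linear unbiased prediction
    (ssGBLUP) for breeding-value estimation combining pedigree, phenotype
    and SNP marker data. Provides two equivalent mixed-model-equation
    formulations: a Woodbury-identity form whose inverse genomic
    relationship products need only an m-by-m marker system (ssGTBLUP),
    and an extended form carrying explicit SNP-effect equations
    (ssSNPBLUP), both solved matrix-free by preconditioned conjugate
    gradient. Includes pedigree relationship algebra (Meuwissen-Luo
    inbreeding, Henderson's sparse A-inverse, Colleau indirect A-times-
    vector products), PLINK 1 binary genotype input and output, residual
    polygenic effects, a J-factor covariate for the pedigree-to-genomic
    base difference, four indirect predictors of genomic breeding values
    for newly genotyped selection candidates (parent average, direct
    genomic value, regression-approximated and exact residual-polygenic
    variants), a gene-dropping breeding-population simulator, and the
    accuracy, dispersion and level-bias comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
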