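Package: apyrel
Title: Reliability Approximation for Single-Step Genomic BLUP with the
    APY Inverse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Approximates theoretical reliabilities (functions of
    prediction error variance) for genomic BLUP and single-step genomic
    BLUP models that use the Algorithm for Proven and Young (APY) sparse
    inverse of the genomic relationship matrix.  Provides exact
    block-sparse extraction of the diagonal of the inverted mixed-model
    system for genotyped animals, an iterative pedigree reliability
    approximation with effective record contributions, Steffensen
    back-solving of record contributions from target reliabilities,
    propagation of genomic information to non-genotyped animals, and a
    multiple-trait adjustment based on the genetic and residual
    covariance matrices.  Includes a synthetic livestock-population
    generator (gene-dropped genotypes, Mendelian-sampling breeding
    values, contemporary-group fixed effects) and dense mixed-model
    oracles for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
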