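Package: pigherit
Title: Pedigree-Based Quantitative Genetics of Pig Behaviour Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Animal-model variance-component estimation for behaviour and
    growth traits recorded on commercial pig herds. Provides pedigree
    validation and numerator-relationship-matrix algebra, restricted
    maximum likelihood (REML) for Gaussian traits with a common-litter
    permanent environmental effect, a threshold (logit liability) model for
    binarised behaviour scores with residual variance fixed at pi^2/3,
    Dempster-Lerner conversion between observed- and liability-scale
    heritability, best linear unbiased prediction of breeding values, k-fold
    cross-validation of breeding-value predictive ability, and a synthetic
    herd generator that emulates the pedigree structure and trait
    distributions of a fattening-pig population for fully reproducible
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
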