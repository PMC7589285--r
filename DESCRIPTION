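Package: cueqg
Title: Quantitative Genetics of Social-Cue Use in Breeding-Site Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating repeatability, additive genetic variance and
    heritability of the use of conspecific and heterospecific social cues
    (neighbourhood abundance and breeding success) in breeding-site choice by
    cavity-nesting birds. Builds distance-weighted neighbourhood cue response
    variables from nest-box records, constructs additive and dominance
    relationship matrices from a pedigree, fits Gaussian mixed models --
    including a joint-phenotype (female plus male) animal model with an
    optional cross-sex additive genetic covariance -- by blocked Gibbs
    sampling with parameter-expanded variance priors, and derives per-draw
    repeatabilities, heritabilities and the total heritability of the joint
    trait with highest-posterior-density summaries. A synthetic-data module
    simulates nest-box landscapes, multi-generation pedigrees, breeding-site
    choices and model-distributed pair phenotypes with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
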