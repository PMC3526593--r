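Package: snpepi
Title: Case-Control SNP Association, Multifactor Dimensionality Reduction,
    and Statistical Epistasis Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for pathway-based genetic analysis of case-control
    studies: marker-level quality control (call rate, minor allele frequency,
    Hardy-Weinberg equilibrium, genomic inflation), per-SNP logistic
    association under codominant and dominant genetic codings with covariate
    adjustment and within-group false discovery rate control, ReliefF/TuRF
    filtered Multifactor Dimensionality Reduction with cross-validation and
    permutation testing, and entropy-based statistical epistasis network
    construction from pairwise information gain. Includes a synthetic
    case-control cohort generator with configurable main effects,
    SNP-by-gender interactions, and penetrance-table epistasis, so every
    stage of the pipeline can be exercised without access to individual-level
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
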