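Package: methtri
Title: Triangulating DNA Methylation as a Mediator of Genetic Disease Liability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether DNA methylation mediates genetic
    liability to a binary trait. Implements the full summary-statistic
    pipeline: trio transmission disequilibrium tests and case-control
    logistic association, fixed-effects inverse-variance meta-analysis and
    LD clumping, cis-mQTL scanning with rank-based inverse-normal
    transformation and covariate residualization, bidirectional two-sample
    Mendelian randomization (Wald ratio, IVW, and a correlated-instrument
    generalized least squares estimator), joint-likelihood colocalization
    with permutation significance, and a per-locus causal-model classifier
    that distinguishes putative mediation/pleiotropy from reverse causation
    and linkage. A synthetic-data module generates haplotype pools with
    block LD, cis-mQTL effects, covariate structure, liability-threshold
    disease, and affected-offspring-ascertained trios under known causal
    models, so the whole pipeline is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
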