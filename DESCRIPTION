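Package: mrchain
Title: Multi-Stage Mendelian Randomization on GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete summary-statistics causal-inference chain for
    two-sample Mendelian randomization studies: instrument selection
    (genome-wide significance, LD clumping, F-statistics, Steiger
    directionality), univariable estimators (Wald ratio, IVW, MR-Egger,
    debiased IVW, robust adjusted profile score) with heterogeneity and
    leave-one-out sensitivity analyses, multivariable IVW, Bayesian
    colocalization via Wakefield approximate Bayes factors,
    summary-data-based MR with HEIDI heterogeneity filtering, cross-trait
    LD score regression, phenome-wide MR screening with FDR control, and
    two-step mediation MR with product-of-coefficients decomposition.
    Includes seeded synthetic-data generators emulating two-sample GWAS
    and molecular-QTL summary statistics with configurable instrument
    strength, pleiotropy, LD structure, heritability and mediation chains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
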