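Package: denovostat
Title: Burden, Bayesian Gene Discovery, and Risk-Gene Estimation for De Novo Variants in Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for de novo coding-variant studies in
    parent-child trio cohorts. Implements callable-base-normalized
    mutation-rate burden tests with one-tailed exact rate-ratio p-values,
    the TADA-Denovo Poisson-Gamma Bayes-factor gene-level test with
    direct-posterior FDR q-values, simulation-based maximum-likelihood
    estimation of the number of risk genes from recurrence, projection of
    risk-gene discovery versus cohort size, and mutability-weighted
    permutation gene-set enrichment. Includes a synthetic trio-cohort
    generator emulating annotated de novo variant tables, per-trio callable
    bases, per-gene mutation-rate tables, and curated gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
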