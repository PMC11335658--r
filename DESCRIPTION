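Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    reporting databases distributed in the FAERS quarterly ASCII format.
    Parses and links the quarterly tables, deduplicates case versions,
    filters to a target drug as primary suspect, maps MedDRA preferred
    terms to system organ classes, builds 2x2 contingency tables at the
    preferred-term and organ-class level (with subgroup analyses), and
    computes four disproportionality statistics: the reporting odds ratio
    (ROR), the proportional reporting ratio (PRR) with chi-squared, the
    Bayesian confidence propagation neural network information component
    (BCPNN IC), and the multi-item gamma Poisson shrinker (MGPS/EBGM) with
    empirical-Bayes hyperparameter estimation. Includes descriptive
    clinical-characteristics summaries (demographics, outcomes,
    time-to-onset, indications) and a synthetic FAERS-like data generator
    with planted signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
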