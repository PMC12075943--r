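Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event reports. Reads quarterly
    "$"-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, INDI, THER),
    deduplicates case versions, matches primary-suspect drugs by generic and
    trade name, maps MedDRA preferred terms to system organ classes, builds
    drug-event 2x2 contingency tables, and computes four disproportionality
    statistics: the reporting odds ratio (ROR), the proportional reporting
    ratio (PRR) with chi-square, the Bayesian confidence propagation neural
    network information component (IC), and the multi-item gamma-Poisson
    shrinker empirical Bayes geometric mean (EBGM) with maximum-likelihood
    hyperparameter estimation. Includes threshold-based signal calling,
    descriptive and subgroup summaries (reporter class, age group, death
    reports, coadministration strata), and a synthetic FAERS-format corpus
    generator with planted drug-event associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
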