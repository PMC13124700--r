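Package: pvdispro
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance disproportionality analysis
    of FAERS-style spontaneous reporting data, built around the quinolone /
    pemphigoid drug-event pair. Provides a synthetic quarterly-file generator
    with known ground-truth association strength, FDA-style case deduplication,
    drug-name standardization and approval-window cohort construction, the
    reporting odds ratio (ROR), proportional reporting ratio (PRR) with
    chi-squared, and Bayesian confidence propagation neural network (BCPNN)
    information component with their published signal criteria, stratified
    subgroup analysis, descriptive cohort profiling, time-to-onset binning, and
    concordance checks against published case series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
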