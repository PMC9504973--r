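Package: pvsignal
Title: Disproportionality and Time-to-Onset Analysis for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting system databases that follow the JADER four-table schema
    (DEMO, DRUG, REAC, HIST). Reads and links the four CSV tables into a
    case-centric database, builds the (case, drug, preferred-term) pair
    table that is the unit of analysis, computes reporting odds ratios
    with Woolf 95% confidence intervals and a lower-bound signal rule,
    fits Weibull models to time-to-onset data with failure-type
    classification from the shape-parameter confidence interval, and
    tabulates post-event outcome proportions. Includes a synthetic
    database generator with planted drug-event associations of known
    reporting odds ratio and onset-delay distribution, so that every
    pipeline stage can be validated without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dialect.R'
    'disproportionality.R'
    'fixtures.R'
    'methods-show.R'
    'outcomes.R'
    'pairs.R'
    'partial-dates.R'
    'pipeline.R'
    'pvsignal-package.R'
    'srs-io.R'
    'synthetic.R'
    'tto.R'
    'utils.R'
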