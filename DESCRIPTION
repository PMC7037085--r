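Package: iemrank
Title: Knowledge-Based Ranking of Inborn Errors of Metabolism from
    Untargeted Metabolomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts untargeted direct-infusion high-resolution mass
    spectrometry (DI-HRMS) metabolomics of a single blood sample into a
    ranked differential diagnosis of inborn errors of metabolism (IEM).
    Implements an expected-library data model with weighted biomarker
    entries, m/z peak annotation against monoisotopic metabolite masses
    at ppm tolerance, per-sample Z-score profiles against control
    samples with signed ranks, an IEM probability score with
    critical-metabolite gating and likelihood classification, cohort
    performance evaluation, and a synthetic-data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'annotation.R'
    'cli.R'
    'evaluation.R'
    'iemrank-package.R'
    'weights.R'
    'library.R'
    'pipeline.R'
    'profile.R'
    'scoring.R'
    'synthetic.R'
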