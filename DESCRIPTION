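Package: bloodsig
Title: Blood Transcriptome Signature Panels for Viral and Bacterial Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and applying small blood-transcriptome
    biomarker panels for infectious and autoimmune disease. Implements
    microarray-style quality control (probe filtering, intensity flooring,
    probe-to-gene aggregation), median-based fold-change and rank-product
    differential expression, cross-dataset frequency ranking and selection of
    virus-response and bacteria-response gene panels, per-sample fold-change
    scoring against the control-group median, k-means discrimination of viral
    versus bacterial dysregulation patterns, single-gene logistic and
    fold-threshold biomarkers, Pearson co-expression networks, sex and age
    covariate checks, longitudinal health monitoring, and a synthetic
    expression-cohort generator with planted ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
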