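Package: longipharm
Title: Longitudinal Pharmacogenomic Analysis of Tumor Evolution and Drug
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal pharmacogenomic analysis of serially
    sampled tumors. Classifies per-patient tumor-evolution types
    (persistence, extinction, expansion) from multi-timepoint somatic
    variant profiles, computes intratumor-heterogeneity (MATH) and
    dN/dS selection statistics, detects evolution-group-specific
    drug-sensitivity shifts between paired timepoints, learns per-drug
    response-prediction models from expression with
    permutation-importance gene signatures, performs preranked gene-set
    enrichment and single-sample gene-set scoring, deconvolves bulk
    expression into drug-tolerant cell-type fractions, scores drug
    combinations (highest-single-agent excess and Chou-Talalay
    combination index), and compares survival between score-defined
    groups. Includes a synthetic-cohort generator with planted ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
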