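Package: pvatlas
Title: Disproportionality Signal Detection and Cross-Drug Similarity
    Analysis for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance toolkit for FAERS-style
    spontaneous-report data: parsing and validation of the quarterly
    "$"-delimited ASCII tables, case-level de-duplication, drug-exposure
    cohort construction with generic/brand name matching and indication
    filtering, four-method disproportionality analysis (proportional
    reporting ratio, reporting odds ratio, the Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma-Poisson shrinker) with concordance-based key-signal calling,
    drug-SOC-PT atlas construction, and cross-drug Jaccard similarity
    networks with classical multidimensional scaling. Includes a
    synthetic FAERS-shaped corpus generator with planted signals and
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
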