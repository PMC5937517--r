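Package: adrmine
Title: Mining Positive and Negative Associations Between Pharmacotherapy
    and Laboratory Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequent-itemset mining over per-patient drug exposure
    transactions combined with a signed chi-square screening statistic
    to detect both positive and negative association rules between drug
    (combination) exposures and laboratory-derived adverse events.
    Includes a configurable severity-grading engine that maps laboratory
    results to graded adverse events, a conventional support/confidence
    Apriori baseline with a rank-sum comparison report, and a synthetic
    cohort generator with planted odds-ratio effects for end-to-end
    validation of the screening pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
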