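Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of spontaneous
    adverse-event reports in the FDA Adverse Event Reporting System (FAERS)
    quarterly-extract format: report deduplication and deletion-list handling,
    case/non-case cohort construction against a preferred-term to system-organ-class
    mapping, reporting odds ratio (ROR) signal screening with count and
    confidence-bound criteria, time-to-onset summaries and rank-sum contrasts,
    cytokine-release-syndrome overlap and per-term mortality tables, and a
    two-stage (univariate screen, multivariate) logistic risk-factor analysis
    over ATC level-1 co-medication classes. Includes a synthetic FAERS-like
    data generator with known ground truth (injected reporting odds, onset
    distributions, fatality model, duplicates and deletions) so every stage is
    testable without access to the real corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
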