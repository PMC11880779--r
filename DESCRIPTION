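Package: landshap
Title: Super-Landmark Survival Models with Shapley Decomposition of
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dynamic short-term cancer risk models from longitudinal
    primary-care-style records using a super-landmark framework: per-age
    eligibility and index dates, lookback-window predictor derivation,
    cluster-robust Cox proportional-hazards fitting with AIC-based
    bidirectional stepwise selection, person-level bootstrap evaluation of
    Harrell's C-index over all combinations of predictor sets, and an
    order-agnostic Shapley decomposition of model discrimination with
    percentile confidence intervals. Includes a synthetic longitudinal
    cohort generator with known ground-truth hazard parameters for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
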