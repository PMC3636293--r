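Package: ceatrial
Title: Trial-Based Cost-Effectiveness and Cost-Utility Analysis for Multi-Arm RCTs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for trial-based economic evaluation of multi-arm randomized
    controlled trials from a societal perspective: valuation of self-reported
    resource use with price-year indexing and defined-daily-dose medication
    costing, single-imputation rules for longitudinal missingness (neighbour
    mean, last observation carried forward, next observation carried backward,
    and a conservative negative scenario for abstinence), EQ-5D-3L utility
    scoring with the Dutch tariff and area-under-the-curve QALYs, incremental
    cost-effectiveness and cost-utility ratios with dominance classification,
    net monetary benefit, nonparametric bootstrap percentile intervals, and
    cost-effectiveness acceptability curves. Includes a seeded synthetic
    three-arm smoking-cessation trial generator so the full pipeline is
    testable without participant-level data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
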