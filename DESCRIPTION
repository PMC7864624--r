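Package: readfusion
Title: Decision-Fusion Protocols for Human-AI Double Reading Teams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of double-reading interaction protocols
    for three-reader diagnostic teams in which a machine classifier acts as the
    second reader. Provides a synthetic reader-panel generator calibrated to a
    multi-reader multi-case knee-MRI annotation study (binary decisions with
    ordinal confidence and perceived case complexity), eight decision-fusion
    protocols (simple, accuracy- and confidence-weighted majority,
    specificity- and sensitivity-oriented arbitration, cautious, presumptuous,
    and the OR rule), six team performance metrics including a
    workload-normalized efficiency, and the two experiments contrasting reader
    teams against a strong benchmark machine and weak against strong teams,
    with one-sample t and exact two-sample Kolmogorov-Smirnov testing under
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
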