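Package: kscreen
Title: Potassium-Efficiency Screening of Rice Varieties from Hydroponic Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for hydroponic screening of rice varieties for
    potassium (K) efficiency. From per-plant trial measurements (morphology,
    tissue dry weights, tissue K concentrations) it computes relative traits,
    a panel of K-efficiency indices (absorption, accumulation, translocation,
    distribution, utilization, response), coefficient-of-variation profiles
    across medium K concentrations, an optimal screening concentration, a
    tolerance ranking with a consistency rule, a tolerant/sensitive parent
    pair for QTL mapping populations, and paired t-test significance
    annotations. A seeded synthetic trial generator with planted genotype
    effects provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
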