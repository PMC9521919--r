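Package: dilicat
Title: Drug-Specific Causality Scoring for Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven causality assessment for drug-induced liver injury
    (DILI). Builds drug-specific phenotypes as empirical quantile profiles of
    three onset features (latency in days, R-value, AST/ALT ratio), allocates
    causality points to candidate cases by proximity to the phenotype's
    percentile bands, doubles the subscore of the feature that best
    discriminates two drugs (lowest Mann-Whitney U), and compares score
    distributions between drugs with a Mantel-Haenszel test for trend on
    five-point ordinal score bins. Includes optional adjudication extensions
    for competing causes and drug hepatotoxicity propensity, a synthetic
    case-series generator with prescribed quantile structure, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
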