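Package: toxsig
Title: Stress-Response Pathway Signatures and Chemical Activation
    Capacity Scoring from Toxicogenomic Fold Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives AhR, Nrf2 and ATF4 stress-response pathway gene
    signatures from condition-level log2 fold-change data using
    pathway-specific activator chemicals and a mean +/- 2 standard
    deviation rule, partitions the three signatures into exclusive and
    overlapping Venn zones, and scores chemicals by a geometric
    "chemical activation capacity": specificity as the absolute cosine
    to a pathway axis, potency as the vector module, and rank as their
    product. Includes condition filtering and category stratification, a
    synthetic fold-change simulator with planted pathway structure for
    end-to-end validation, tidy readers and writers for fold-change
    tables, gene target catalogs and activator configurations, and a
    single-command pipeline with auditable selection reports.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
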