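Package: netpharm
Title: Network Pharmacology Screening of Phytochemical Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for network-pharmacology screening of
    isolated phytochemicals: quantitative estimate of drug-likeness (QED) and
    Veber oral-bioavailability filtering, compound-target and disease gene-set
    intersection, protein-protein interaction (PPI) topology with
    Cytoscape-convention centralities and key-target selection, DAVID-style
    (EASE / hypergeometric) over-representation analysis, and integrated
    compound-target-pathway network construction. Also provides theoretical
    monoisotopic adduct m/z calculation for negative-mode HR-ESI-MS
    assignments, a fully seeded synthetic-data generator with planted,
    recoverable structure for end-to-end validation, and a one-call pipeline
    runner with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
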