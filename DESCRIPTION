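Package: pmcindex
Title: Policy Modeling Consistency (PMC) Index Evaluation Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Schema-driven evaluation of policy texts with the Policy Modeling
    Consistency (PMC) index: binary secondary-variable scoring against an
    indicator schema, equal-weight aggregation to primary-variable scores,
    PMC index computation with grade classification and ranking, 3x3 PMC
    surface matrices with concavity reports and surface/radar figures,
    gap-based improvement-path ordering, and keyword co-occurrence network
    analysis of policy corpora. Ships a complete worked example: an indicator
    system of 9 primary and 33 binary secondary variables and the full
    10-policy binary score table for Chinese smart older-adults-care policies,
    plus seeded synthetic generators for score tables and corpora.
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
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
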