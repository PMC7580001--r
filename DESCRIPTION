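Package: domainburden
Title: Protein-Domain Aggregation Analysis of Somatic Mutations in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-domain families recurrently hit by infrequent
    somatic mutations in a tumor cohort. Tallies missense mutations falling in
    domain-encoding regions across all genes carrying a domain family and
    computes an exact Poisson-binomial tail p-value by dynamic programming,
    followed by a three-part recurrence screen (genome coverage, p-value,
    normalized Shannon entropy). Also provides per-gene mutation coverage and
    stage-enrichment statistics, a subsample-consensus harness around any
    per-gene significance test, projection of domain mutations onto multiple
    alignment columns, survival stratification by mutation-carrier status, and
    a seeded synthetic-cohort generator so every stage is testable without
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    IRanges,
    S4Vectors,
    Biostrings,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
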