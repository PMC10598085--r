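Package: clp1family
Title: Classification and Domain-Architecture Analysis of Clp1 Family
    Polynucleotide Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for the eukaryotic
    Clp1/Nol9/Grc3 polynucleotide-kinase (PNK) protein family: seeded
    local-alignment homolog search with dual full-length/kinase-domain
    queries, per-species inventories, greedy representative clustering,
    progressive multiple alignment with 12-rank conservation scoring,
    gap trimming, neighbor-joining trees with bootstrap support and
    midpoint rooting, profile-based domain annotation with de novo
    discovery of novel conserved domains, clade-based group and type
    classification, Walker A/Walker B/Clasp/Lid motif scanning, and
    motif-based PNK-activity prediction.  A synthetic-proteome simulator
    with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
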