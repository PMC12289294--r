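Package: aeminer
Title: Mining Adverse-Event Mentions of GLP-1 Receptor Agonists from Social-Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for lexicon-based extraction of
    adverse-event mentions from public social-media posts about GLP-1
    receptor agonist weight-loss medications (semaglutide, tirzepatide and
    their brands). Provides corpus ingestion with study inclusion filters
    (date range, page-admin country, exact-duplicate removal), drug and
    adverse-event term matching with exclusive drug-category assignment,
    per-drug frequency and percentage tables, monthly temporal trend series
    with key-event annotation, and a weighted adverse-event co-occurrence
    network analysed with an in-package Louvain modularity optimiser,
    exhaustive-partition oracle, and seeded Fruchterman-Reingold layout.
    Includes a synthetic corpus generator with a ground-truth ledger
    (drug shares, per-drug adverse-event rates, planted co-mention
    clusters, duplicates, off-filter noise) that emulates the structure of
    a CrowdTangle-style Facebook export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    stringr,
    readr,
    rlang,
    jsonlite,
    igraph,
    withr,
    ggplot2,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
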