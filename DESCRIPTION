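Package: vertiseq
Title: Vaginal Microbiota Succession and Mother-to-Child Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 16S rRNA OTU tables from longitudinal
    mother-child cohorts: sample depth filtering and rarefaction, alpha and
    beta diversity (richness, Shannon, Faith's phylogenetic diversity,
    UniFrac, Jensen-Shannon divergence), principal coordinates analysis and
    sequential PERMANOVA, compartment-sharing partitions and SparCC
    co-occurrence networks, genus-level rank tests with false discovery rate
    control, and a per-OTU Fisher presence/absence transfer scan summarised
    by a weighted-ratio (WR) enrichment statistic with a permutation null.
    Includes a Dirichlet-multinomial cohort simulator with ground truth so
    the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    phangorn,
    phyloseq,
    biomformat
Config/testthat/edition: 3
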