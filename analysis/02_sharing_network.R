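#!/usr/bin/env Rscript
# Stage 2: which OTUs are shared between the mother's vagina and the
# child's gut and airways, and how do OTUs co-occur within compartments?
#
# Outputs: results/partition.json (7-region Venn partition with read
# fractions), results/edges.tsv (SparCC co-occurrence edges, r > 0.2,
# max across compartments).

suppressPackageStartupMessages(library(vertiseq))

dir <- file.path("results", "data", "null")
tab <- read_count_table(file.path(dir, "counts.tsv"),
                        file.path(dir, "metadata.tsv"))
tab <- filter_low_depth(tab, 2000, quiet = TRUE)

part <- compartment_partition(tab)
ubiq <- part[part$region == "vaginal+feces+airway", ]
cat(sprintf("ubiquitous OTUs (all three compartments): %d of %d, carrying %.1f%% of reads\n",
            ubiq$n_otus, sum(part$n_otus), 100 * ubiq$read_fraction))
jsonlite::write_json(part[, c("region", "n_otus", "read_fraction")],
                     "results/partition.json", dataframe = "rows",
                     auto_unbox = TRUE, digits = NA)

corrs <- lapply(stats::setNames(nm = c("vaginal", "feces", "airway")),
                function(cp) {
  sub <- subset_samples(tab, tab$metadata$compartment == cp,
                        drop_empty_otus = TRUE)
  keep <- utils::head(order(rowSums(sub$counts), decreasing = TRUE), 150)
  sub$counts <- sub$counts[keep, , drop = FALSE]
  sparcc_correlation(sub, seed = 101)
})
edges <- cooccurrence_edges(corrs, threshold = 0.2)
vertiseq:::write_tsv_lf(edges, "results/edges.tsv")
cat(sprintf("co-occurrence network: %d edges with r > 0.2 (max over compartments)\n",
            nrow(edges)))
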