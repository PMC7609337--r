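#!/usr/bin/env Rscript
# Stage 4: genus-level succession across the vaginal timepoints and OTUs
# appearing for the first time in the birth samples.
#
# Outputs: results/genus_tests.tsv, results/birth_unique.json.

suppressPackageStartupMessages(library(vertiseq))

dir <- file.path("results", "data", "null")
tab <- filter_low_depth(
  read_count_table(file.path(dir, "counts.tsv"), file.path(dir, "metadata.tsv")),
  2000, quiet = TRUE)
tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))

vaginal <- subset_samples(tab, tab$metadata$compartment == "vaginal")
gen <- relative_abundance(aggregate_by_rank(vaginal, tax, "genus"))
tests <- genus_timepoint_tests(gen, top_n = 15)
vertiseq:::write_tsv_lf(tests, "results/genus_tests.tsv")
cat(sprintf("top %d genera tested across w24/w36/birth (Kruskal-Wallis, BH within set):\n",
            nrow(tests)))
sig <- tests[tests$q < 0.05, ]
cat(sprintf("  %d genera at q < 0.05; directions: %s\n", nrow(sig),
            paste(sprintf("%s (%s)", sig$genus, sig$direction), collapse = ", ")))
lac <- tests[tests$genus == "Lactobacillus", ]
if (nrow(lac)) {
  cat(sprintf("  Lactobacillus median relative abundance: w24 %.3f -> w36 %.3f -> birth %.3f (%s, q = %.3g)\n",
              lac$median_w24, lac$median_w36, lac$median_birth,
              lac$direction, lac$q))
}

bu <- birth_unique_otus(vaginal, min_prevalence = 5)
cat(sprintf("birth-unique OTUs: %d total, %d in >= 5 birth samples; combined relative abundance median %.4f%% [IQR %.4f-%.4f%%]\n",
            length(bu$otus), length(bu$prevalent_otus),
            100 * bu$summary["median"], 100 * bu$summary["iqr_lo"],
            100 * bu$summary["iqr_hi"]))
jsonlite::write_json(
  list(n_unique = length(bu$otus), prevalent_otus = bu$prevalent_otus,
       combined_rel_abundance = as.list(bu$summary)),
  "results/birth_unique.json", auto_unbox = TRUE, digits = NA)
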