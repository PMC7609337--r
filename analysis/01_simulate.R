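#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohorts every later stage consumes.
#
# Two cohorts at the study design scale (57 dyads; vaginal w24/w36/birth +
# child feces/airway at week 1; 300 OTUs):
#   - a null cohort with no vertical transfer (transfer_pi = 0)
#   - a signal cohort with transfer mixing weight 0.3 on the
#     Lactobacillales / Clostridiales / Enterobacteriales clades
# Read depths use the fast preset (lognormal, median ~2000 reads); the
# simulated structure (declining Lactobacillus dominance, subject
# signatures, clade-structured transfer) does not depend on depth scale.

suppressPackageStartupMessages(library(vertiseq))

dp <- depth_preset("test")
for (preset in c("null", "signal")) {
  pi <- if (preset == "signal") 0.3 else 0
  cfg <- cohort_config(n_dyads = 57, n_otus = 300,
                       depth_log_mean = dp$depth_log_mean,
                       depth_log_sd = dp$depth_log_sd,
                       transfer_pi = pi, seed = 20240 + (pi > 0))
  coh <- simulate_cohort(cfg)
  dir <- file.path("results", "data", preset)
  write_cohort(coh, dir)
  depths <- sample_depths(coh$table)
  cat(sprintf("[%s] %d samples, %d OTUs, median depth %d reads -> %s\n",
              preset, ncol(coh$table$counts), nrow(coh$table$counts),
              round(stats::median(depths)), dir))
}
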