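#!/usr/bin/env Rscript
# Stage 3: alpha diversity over pregnancy, its split between individual
# mother and timepoint, and the vaginal beta-diversity structure
# (unweighted UniFrac -> PCoA -> sequential PERMANOVA).
#
# Outputs under results/: alpha.tsv, alpha_anova_<metric>.tsv,
# distance_unweighted_unifrac.tsv, pcoa_unweighted_unifrac.tsv,
# permanova_unweighted_unifrac.tsv, pco_axis_r2.tsv.

suppressPackageStartupMessages(library(vertiseq))

dir <- file.path("results", "data", "null")
tab <- filter_low_depth(
  read_count_table(file.path(dir, "counts.tsv"), file.path(dir, "metadata.tsv")),
  2000, quiet = TRUE)
tree <- read_tree(file.path(dir, "tree.nwk"))

alpha <- alpha_diversity_table(tab, c("richness", "shannon", "faith_pd"), tree)
vertiseq:::write_tsv_lf(alpha, "results/alpha.tsv")
med <- stats::aggregate(cbind(richness, shannon, faith_pd) ~ compartment,
                        alpha, stats::median)
cat("median per-sample alpha diversity by compartment:\n")
print(med, row.names = FALSE)

va <- alpha[alpha$compartment == "vaginal", ]
for (m in c("shannon", "faith_pd")) {
  dec <- alpha_variance_decomposition(va[[m]], va$subject_id, va$timepoint)
  vertiseq:::write_tsv_lf(dec, sprintf("results/alpha_anova_%s.tsv", m))
  cat(sprintf("%s: %.1f%% of variation allocated to individual mother (p = %.3g), %.1f%% to timepoint (p = %.3g)\n",
              m, 100 * dec$fraction[dec$term == "subject"],
              dec$p[dec$term == "subject"],
              100 * dec$fraction[dec$term == "timepoint"],
              dec$p[dec$term == "timepoint"]))
}

vaginal <- subset_samples(tab, tab$metadata$compartment == "vaginal")
d <- distance_matrix(vaginal, "unweighted_unifrac", tree)
utils::write.table(as.matrix(d), "results/distance_unweighted_unifrac.tsv",
                   sep = "\t", quote = FALSE)
ord <- pcoa_ordination(d)
vertiseq:::write_tsv_lf(
  data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
             check.names = FALSE),
  "results/pcoa_unweighted_unifrac.tsv")

pmv <- permanova(d, list(timepoint = vaginal$metadata$timepoint,
                         individual = vaginal$metadata$subject_id),
                 n_perm = 999, seed = 202)
vertiseq:::write_tsv_lf(pmv, "results/permanova_unweighted_unifrac.tsv")
tp <- pmv[pmv$term == "timepoint", ]; ind <- pmv[pmv$term == "individual", ]
cat(sprintf("PERMANOVA (sequential): timepoint F = %.2f, R2 = %.1f%%, p = %.3g; individual F = %.2f, R2 = %.1f%%, p = %.3g\n",
            tp$f, 100 * tp$fraction, tp$p, ind$f, 100 * ind$fraction, ind$p))

axis_rows <- do.call(rbind, lapply(1:2, function(ax) {
  r_tp <- coordinate_factor_r2(ord, ax, vaginal$metadata$timepoint)
  r_ind <- coordinate_factor_r2(ord, ax, vaginal$metadata$subject_id)
  data.frame(axis = paste0("PCo", ax),
             r2_timepoint = r_tp$r2, p_timepoint = r_tp$p,
             r2_individual = r_ind$r2, p_individual = r_ind$p)
}))
vertiseq:::write_tsv_lf(axis_rows, "results/pco_axis_r2.tsv")
cat(sprintf("PCo2 variation explained by individual mother: %.1f%%\n",
            100 * axis_rows$r2_individual[2]))
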