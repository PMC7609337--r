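#' Validate a pipeline run configuration
#'
#' @param counts,metadata paths to the count and metadata TSVs.
#' @param tree optional path to a Newick tree (required when any UniFrac
#'   metric or Faith's PD is requested).
#' @param taxonomy optional path to a taxonomy TSV (required for the genus
#'   tests).
#' @param out_dir output directory (created if missing).
#' @param min_reads depth filter threshold (default 2000).
#' @param metrics beta-diversity metrics to compute (default unweighted
#'   UniFrac plus Jensen-Shannon divergence).
#' @param n_perm permutations for PERMANOVA and the transfer tests
#'   (default 999).
#' @param seed master seed; stage seeds are derived as `seed + 0, 1, 2, ...`
#'   in the order recorded in the manifest.
#' @param delivery_mode restrict the transfer analyses to dyads with this
#'   delivery mode when the metadata has a `delivery_mode` column
#'   (default `"vaginal"`).
#' @param sparcc_max_otus cap on OTUs entering the SparCC network per
#'   compartment (the most abundant are kept); keeps the network stage
#'   tractable on large tables.
#' @return validated `run_config` list.
#' @export
run_config <- function(counts, metadata, tree = NULL, taxonomy = NULL,
                       out_dir = "results", min_reads = 2000,
                       metrics = c("unweighted_unifrac", "jsd"),
                       n_perm = 999, seed = 1,
                       delivery_mode = "vaginal",
                       sparcc_max_otus = 150) {
  for (p in c(counts, metadata, tree, taxonomy)) {
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
  }
  metrics <- match.arg(metrics, c("unweighted_unifrac", "weighted_unifrac",
                                  "jaccard", "bray_curtis", "jsd"),
                       several.ok = TRUE)
  if (any(grepl("unifrac", metrics)) && is.null(tree)) {
    stop("UniFrac metrics requested but no tree supplied")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: depth filter; compartment-sharing partition and
#' SparCC co-occurrence network; alpha diversity with its subject/timepoint
#' variance decomposition; beta diversity, PCoA and sequential PERMANOVA of
#' the vaginal samples; genus-level timepoint tests; and the transfer suite
#' (per-OTU Fisher scan, WR permutation test, abundance-odds correlation,
#' phylogenetic signal and dyad-distance test) for each child compartment.
#' All stage outputs are written as TSV/JSON under `config$out_dir`, plus a
#' `manifest.json` recording the configuration, derived seeds and per-stage
#' row counts. Reruns with the same config reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[!vapply(config, is.null, TRUE)],
                   package_version = as.character(utils::packageVersion("vertiseq")),
                   seeds = list(sparcc = config$seed + 1,
                                permanova = config$seed + 2,
                                transfer = config$seed + 3),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tab <- stage("read", read_count_table(config$counts, config$metadata))
  tree <- if (!is.null(config$tree)) stage("read", read_tree(config$tree))
  tax <- if (!is.null(config$taxonomy)) stage("read", read_taxonomy(config$taxonomy))

  tab <- stage("filter", filter_low_depth(tab, config$min_reads, quiet = TRUE))
  manifest$stages$filter <- list(samples_kept = ncol(tab$counts),
                                 samples_removed = length(attr(tab, "removed_samples")))

  # --- sharing partition + co-occurrence network ---------------------
  part <- stage("partition", compartment_partition(tab))
  part_out <- part[, c("region", "n_otus", "read_fraction")]
  jsonlite::write_json(part_out, file.path(config$out_dir, "partition.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  corrs <- stage("network", {
    lapply(stats::setNames(nm = c("vaginal", "feces", "airway")), function(cp) {
      sub <- subset_samples(tab, tab$metadata$compartment == cp,
                            drop_empty_otus = TRUE)
      keep <- utils::head(order(rowSums(sub$counts), decreasing = TRUE),
                          config$sparcc_max_otus)
      sub$counts <- sub$counts[keep, , drop = FALSE]
      sparcc_correlation(sub, seed = config$seed + 1)
    })
  })
  edges <- cooccurrence_edges(corrs, threshold = 0.2)
  write_tsv_lf(edges, file.path(config$out_dir, "edges.tsv"))
  manifest$stages$network <- list(n_edges = nrow(edges))

  # --- diversity ------------------------------------------------------
  vaginal <- subset_samples(tab, tab$metadata$compartment == "vaginal")
  alpha_metrics <- c("richness", "shannon", if (!is.null(tree)) "faith_pd")
  alpha <- stage("alpha", alpha_diversity_table(tab, alpha_metrics, tree))
  write_tsv_lf(alpha, file.path(config$out_dir, "alpha.tsv"))
  va <- alpha[alpha$compartment == "vaginal", ]
  decomp <- lapply(stats::setNames(nm = setdiff(alpha_metrics, "richness")),
                   function(m) {
    alpha_variance_decomposition(va[[m]], va$subject_id, va$timepoint)
  })
  for (m in names(decomp)) {
    write_tsv_lf(decomp[[m]], file.path(config$out_dir,
                                        paste0("alpha_anova_", m, ".tsv")))
  }
  for (met in config$metrics) {
    dmat <- stage("beta", distance_matrix(vaginal, met, tree))
    utils::write.table(as.matrix(dmat),
                       file.path(config$out_dir, paste0("distance_", met, ".tsv")),
                       sep = "\t", quote = FALSE)
    ord <- pcoa_ordination(dmat)
    write_tsv_lf(data.frame(sample_id = rownames(ord$coordinates),
                            ord$coordinates, check.names = FALSE),
                 file.path(config$out_dir, paste0("pcoa_", met, ".tsv")))
    pmv <- stage("permanova",
                 permanova(dmat, list(timepoint = vaginal$metadata$timepoint,
                                      individual = vaginal$metadata$subject_id),
                           n_perm = config$n_perm, seed = config$seed + 2))
    write_tsv_lf(pmv, file.path(config$out_dir, paste0("permanova_", met, ".tsv")))
  }
  manifest$stages$diversity <- list(n_vaginal = ncol(vaginal$counts),
                                    metrics = config$metrics)

  # --- genus-level tests ---------------------------------------------
  if (!is.null(tax)) {
    gen <- aggregate_by_rank(vaginal, tax, "genus")
    gtests <- stage("taxa", genus_timepoint_tests(relative_abundance(gen)))
    write_tsv_lf(gtests, file.path(config$out_dir, "genus_tests.tsv"))
    manifest$stages$taxa <- list(n_genera = nrow(gtests))
  }

  # --- transfer -------------------------------------------------------
  md <- tab$metadata
  keep_subj <- if ("delivery_mode" %in% names(md)) {
    unique(md$subject_id[md$delivery_mode == config$delivery_mode])
  } else unique(md$subject_id)
  births <- md$sample_id[md$compartment == "vaginal" & md$timepoint == "birth" &
                           md$subject_id %in% keep_subj]
  mom_tab <- subset_samples(tab, births)
  for (comp in c("feces", "airway")) {
    ch_ids <- md$sample_id[md$compartment == comp & md$subject_id %in% keep_subj]
    ch_tab <- subset_samples(tab, ch_ids)
    common <- intersect(mom_tab$metadata$subject_id, ch_tab$metadata$subject_id)
    dyads <- stats::setNames(
      ch_tab$metadata$sample_id[match(common, ch_tab$metadata$subject_id)],
      mom_tab$metadata$sample_id[match(common, mom_tab$metadata$subject_id)])
    if (length(dyads) < 3) next
    wrt <- stage("transfer",
                 wr_permutation_test(mom_tab, ch_tab, dyads,
                                     B = config$n_perm, seed = config$seed + 3))
    scan <- wrt$scan
    write_tsv_lf(scan, file.path(config$out_dir, paste0("scan_", comp, ".tsv")))
    volcano <- data.frame(otu = scan$otu,
                          or_display = truncate_or_for_display(scan$or),
                          p = scan$p, carriers = scan$carriers)
    write_tsv_lf(volcano, file.path(config$out_dir, paste0("volcano_", comp, ".tsv")))
    ab <- if (nrow(scan) >= 4) {
      abundance_odds_correlation(scan, relative_abundance(mom_tab))
    }
    ph <- if (!is.null(tree) && nrow(scan) >= 4) {
      phylo_signal_of_transfer(scan, tree, B = config$n_perm,
                               seed = config$seed + 3)
    }
    dy <- dyad_distance_test(mom_tab, ch_tab, dyads, metric = "jsd",
                             tree = tree, B = config$n_perm,
                             seed = config$seed + 3)
    jsonlite::write_json(
      list(compartment = comp, n_dyads = length(dyads),
           wr = wrt$wr, p = wrt$p, B = wrt$B, n_otus = wrt$n_otus,
           abundance_odds = ab,
           phylo_signal = ph,
           dyad_jsd = list(observed = dy$observed, p = dy$p)),
      file.path(config$out_dir, paste0("transfer_", comp, ".json")),
      auto_unbox = TRUE, digits = NA)
    manifest$stages[[paste0("transfer_", comp)]] <-
      list(n_dyads = length(dyads), n_otus = wrt$n_otus, wr = wrt$wr, p = wrt$p)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Write a simulated cohort to disk
#'
#' Writes `counts.tsv`, `metadata.tsv`, `tree.nwk`, `taxonomy.tsv` and
#' `truth.json` under `dir`, the file layout [run_config()] reads back.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(cohort$table, file.path(dir, "counts.tsv"),
                    file.path(dir, "metadata.tsv"))
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  write_tsv_lf(as.data.frame(cohort$taxonomy), file.path(dir, "taxonomy.tsv"))
  jsonlite::write_json(
    list(transfer_pi = cohort$truth$transfer_pi,
         transfer_prone = as.list(cohort$truth$transfer_prone),
         clade = as.list(cohort$truth$clade)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
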