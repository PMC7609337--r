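#' Configuration for the synthetic mother-child cohort
#'
#' Collects and validates the parameters of [simulate_cohort()]. The
#' defaults emulate a pregnancy cohort of 57 mother-child dyads sampled in
#' the vagina at pregnancy weeks 24 and 36 and at birth, with the child's
#' feces and airways sampled at one week of age: Lactobacillus-dominated
#' vaginal communities whose dominance declines toward birth, a persistent
#' subject-specific signature, and (optionally) vertical transfer of
#' phylogenetically clustered clades into the child samples.
#'
#' @param n_dyads number of mother-child pairs (default 57).
#' @param n_otus number of OTUs (default 300).
#' @param depth_log_mean,depth_log_sd lognormal read-depth parameters on the
#'   natural-log scale. The defaults give a median depth of ~40,000 reads;
#'   use [depth_preset()]`("test")` for a median of ~2,000.
#' @param lacto_frac_w24 expected Lactobacillus-clade share of the vaginal
#'   community at week 24 (default 0.8).
#' @param lacto_decline per-timepoint drop of that share on the logit scale
#'   (default 0.5), giving the gradual decline toward birth.
#' @param subject_sd SD of the subject random effect on log relative
#'   abundance (default 1), shared across a mother's vaginal timepoints.
#' @param transfer_pi mixing weight in \[0, 1\] of the mother's birth
#'   community (masked to transfer-prone OTUs) in her child's expected
#'   composition. 0 = no vertical transfer (the null); 0.3 is the signal
#'   preset used for power checks.
#' @param transfer_clades clade labels designated transfer-prone (defaults
#'   to the Lactobacillales-, Clostridiales- and Enterobacteriales-like
#'   clades of [simulate_tree()]).
#' @param overdispersion Dirichlet precision of the count noise
#'   (Dirichlet-multinomial; default 200).
#' @param feces_richness,airway_richness fraction of OTUs in the child
#'   feces/airway environmental pools (airway pool sparser, echoing the
#'   lower richness of early airway communities).
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 57, n_otus = 300,
                          depth_log_mean = log(40000), depth_log_sd = 0.35,
                          lacto_frac_w24 = 0.8, lacto_decline = 0.5,
                          subject_sd = 1,
                          transfer_pi = 0,
                          transfer_clades = c("Lactobacillales",
                                              "Clostridiales",
                                              "Enterobacteriales"),
                          overdispersion = 200,
                          feces_richness = 0.6, airway_richness = 0.3,
                          seed = 1) {
  stopifnot(n_dyads >= 2, n_otus >= 10,
            lacto_frac_w24 > 0, lacto_frac_w24 < 1,
            transfer_pi >= 0, transfer_pi <= 1,
            subject_sd >= 0, overdispersion > 0,
            feces_richness > 0, feces_richness <= 1,
            airway_richness > 0, airway_richness <= 1)
  if (transfer_pi > 0 && length(transfer_clades) == 0) {
    stop("transfer_pi > 0 requires at least one transfer-prone clade")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Lognormal depth presets
#'
#' @param preset `"study"` (median depth ~40,000 reads, the scale of the
#'   cohort the simulator emulates) or `"test"` (median ~2,000, for fast
#'   simulation studies).
#' @return list with `depth_log_mean` and `depth_log_sd`.
#' @export
depth_preset <- function(preset = c("study", "test")) {
  preset <- match.arg(preset)
  switch(preset,
    study = list(depth_log_mean = log(40000), depth_log_sd = 0.35),
    test = list(depth_log_mean = log(2000), depth_log_sd = 0.35)
  )
}

#' Simulate a mother-child cohort with ground truth
#'
#' Every dyad contributes five samples: vaginal w24, w36 and birth, child
#' feces and child airway at week 1. Expected vaginal compositions put a
#' share `plogis(qlogis(lacto_frac_w24) - lacto_decline * t)` (t = 0, 1, 2)
#' on the Lactobacillus-like clade, distributed within clades by a cohort
#' base profile perturbed by subject-specific lognormal offsets. Child
#' expected compositions mix the mother's birth composition, masked to the
#' transfer-prone OTUs and renormalised, with a compartment-specific
#' environmental pool: `pi * masked_mother + (1 - pi) * pool`. Counts are
#' Dirichlet-multinomial draws at lognormal depths.
#'
#' Randomness: the tree is drawn with `seed` and everything else with
#' `seed + 1`, so a cohort is fully reproducible from its config.
#'
#' @param config a [cohort_config()].
#' @return list with `table` (a [count_table()]), `tree` (`phylo`),
#'   `taxonomy` (a [taxonomy()]) and `truth` (list: `transfer_pi`,
#'   `transfer_prone` logical per OTU, `clade` per OTU, `subject_effects`
#'   matrix, and the expected compositions used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  sim_tree <- simulate_tree(cfg$n_otus, seed = cfg$seed)
  tree <- sim_tree$tree
  clade <- sim_tree$clade
  otus <- tree$tip.label
  n_otu <- cfg$n_otus
  n_dy <- cfg$n_dyads
  transfer_prone <- clade %in% cfg$transfer_clades
  if (cfg$transfer_pi > 0 && !any(transfer_prone)) {
    stop("no OTU belongs to a transfer-prone clade")
  }
  set.seed(cfg$seed + 1)

  lacto <- clade == "Lactobacillales"
  # cohort-level base profile on the log scale
  base_log <- stats::rnorm(n_otu, 0, 1)
  # subject offsets, shared across that subject's vaginal timepoints
  subj_eff <- matrix(stats::rnorm(n_dy * n_otu, 0, cfg$subject_sd),
                     n_dy, n_otu)
  lacto_share <- stats::plogis(stats::qlogis(cfg$lacto_frac_w24) -
                                 cfg$lacto_decline * (0:2))

  # environmental pools for the child compartments, fixed per cohort
  pool_of <- function(frac) {
    support <- sample.int(n_otu, max(4L, round(frac * n_otu)))
    w <- numeric(n_otu)
    w[support] <- stats::rgamma(length(support), 1)
    w / sum(w)
  }
  feces_pool <- pool_of(cfg$feces_richness)
  airway_pool <- pool_of(cfg$airway_richness)

  timepoints <- c("w24", "w36", "birth")
  n_samp <- n_dy * 5L
  counts <- matrix(0, n_otu, n_samp, dimnames = list(otus, NULL))
  md <- data.frame(sample_id = character(n_samp), subject_id = character(n_samp),
                   compartment = character(n_samp), timepoint = character(n_samp),
                   delivery_mode = "vaginal", stringsAsFactors = FALSE)
  expected <- matrix(0, n_otu, n_samp)

  subj_ids <- sprintf("D%03d", seq_len(n_dy))
  col <- 0L
  birth_expected <- matrix(0, n_otu, n_dy)
  for (s in seq_len(n_dy)) {
    w <- exp(base_log + subj_eff[s, ])
    for (t in 1:3) {
      e <- numeric(n_otu)
      if (any(lacto)) {
        e[lacto] <- lacto_share[t] * w[lacto] / sum(w[lacto])
      }
      e[!lacto] <- (1 - lacto_share[t]) * w[!lacto] / sum(w[!lacto])
      col <- col + 1L
      expected[, col] <- e
      md[col, 1:4] <- c(sprintf("%s_V_%s", subj_ids[s], timepoints[t]),
                        subj_ids[s], "vaginal", timepoints[t])
      if (t == 3L) birth_expected[, s] <- e
    }
  }
  for (s in seq_len(n_dy)) {
    masked <- birth_expected[, s] * transfer_prone
    if (sum(masked) > 0) masked <- masked / sum(masked)
    for (comp in c("feces", "airway")) {
      pool <- if (comp == "feces") feces_pool else airway_pool
      e <- cfg$transfer_pi * masked + (1 - cfg$transfer_pi) * pool
      col <- col + 1L
      expected[, col] <- e
      md[col, 1:4] <- c(sprintf("%s_C_%s", subj_ids[s], comp),
                        subj_ids[s], comp, "week1")
    }
  }

  depths <- pmax(1, round(stats::rlnorm(n_samp, cfg$depth_log_mean,
                                        cfg$depth_log_sd)))
  for (j in seq_len(n_samp)) {
    shape <- cfg$overdispersion * expected[, j]
    g <- numeric(n_otu)
    pos <- shape > 0
    g[pos] <- stats::rgamma(sum(pos), shape = shape[pos])
    if (sum(g) == 0) g[pos] <- expected[pos, j]
    p <- g / sum(g)
    counts[, j] <- stats::rmultinom(1, size = depths[j], prob = p)
  }
  colnames(counts) <- md$sample_id

  tax <- clade_taxonomy(otus, clade)
  truth <- list(transfer_pi = cfg$transfer_pi,
                transfer_prone = stats::setNames(transfer_prone, otus),
                clade = clade,
                subject_effects = subj_eff,
                expected = expected,
                feces_pool = feces_pool, airway_pool = airway_pool)
  list(table = count_table(counts, md), tree = tree, taxonomy = tax,
       truth = truth)
}

# Order/genus-style taxonomy labels per simulated clade. Two thirds of the
# Lactobacillales clade is labelled genus Lactobacillus so that genus-level
# summaries show the expected dominant genus.
clade_taxonomy <- function(otus, clade) {
  genus_pool <- list(
    Lactobacillales = c("Lactobacillus", "Lactobacillus", "Streptococcus",
                        "Enterococcus", "Gemella"),
    Clostridiales = c("Clostridium", "Blautia", "Faecalibacterium"),
    Enterobacteriales = c("Escherichia", "Klebsiella", "Enterobacter"),
    Bacteroidales = c("Bacteroides", "Prevotella"),
    Pseudomonadales = c("Moraxella", "Pseudomonas", "Acinetobacter")
  )
  class_of <- c(Lactobacillales = "Bacilli", Clostridiales = "Clostridia",
                Enterobacteriales = "Gammaproteobacteria",
                Bacteroidales = "Bacteroidia",
                Pseudomonadales = "Gammaproteobacteria")
  phylum_of <- c(Lactobacillales = "Firmicutes", Clostridiales = "Firmicutes",
                 Enterobacteriales = "Proteobacteria",
                 Bacteroidales = "Bacteroidetes",
                 Pseudomonadales = "Proteobacteria")
  genus <- character(length(otus))
  for (cl in unique(clade)) {
    idx <- which(clade == cl)
    pool <- genus_pool[[cl]]
    genus[idx] <- pool[((seq_along(idx) - 1L) %% length(pool)) + 1L]
  }
  taxonomy(data.frame(
    otu_id = otus, kingdom = "Bacteria",
    phylum = unname(phylum_of[clade]), class = unname(class_of[clade]),
    order = unname(clade), family = paste0(clade, "aceae"), genus = genus,
    stringsAsFactors = FALSE
  ))
}
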