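# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately use different code paths (choose()-based enumeration,
# phangorn tree traversal, direct sums-of-squares arithmetic) than the
# implementations they check.

# -- fixtures ---------------------------------------------------------------

make_metadata <- function(sample_ids, subject_ids, compartment, timepoint) {
  data.frame(sample_id = sample_ids, subject_id = subject_ids,
             compartment = compartment, timepoint = timepoint,
             stringsAsFactors = FALSE)
}

# tiny vaginal-only table: n_sub subjects x 3 timepoints
make_vaginal_table <- function(counts, n_sub) {
  tps <- rep(c("w24", "w36", "birth"), n_sub)
  subj <- rep(sprintf("S%02d", seq_len(n_sub)), each = 3)
  ids <- paste(subj, tps, sep = "_")
  colnames(counts) <- ids
  count_table(counts, make_metadata(ids, subj, "vaginal", tps))
}

# mother birth samples + child samples of one compartment, plus dyad map
make_dyad_tables <- function(mom_counts, child_counts, compartment = "feces") {
  n <- ncol(mom_counts)
  subj <- sprintf("S%02d", seq_len(n))
  mids <- paste0(subj, "_birth"); cids <- paste0(subj, "_child")
  colnames(mom_counts) <- mids
  colnames(child_counts) <- cids
  mom <- count_table(mom_counts, make_metadata(mids, subj, "vaginal", "birth"))
  ch <- count_table(child_counts,
                    make_metadata(cids, subj, compartment, "week1"))
  list(mom = mom, child = ch, dyads = stats::setNames(cids, mids))
}

small_cohort <- function(seed, n_dyads = 12, n_otus = 40, transfer_pi = 0, ...) {
  dp <- depth_preset("test")
  simulate_cohort(cohort_config(
    n_dyads = n_dyads, n_otus = n_otus,
    depth_log_mean = dp$depth_log_mean, depth_log_sd = dp$depth_log_sd,
    transfer_pi = transfer_pi, seed = seed, ...))
}

cohort_dyads <- function(coh, compartment = "feces") {
  md <- coh$table$metadata
  mom <- subset_samples(coh$table, md$sample_id[md$timepoint == "birth"])
  ch <- subset_samples(coh$table,
                       md$sample_id[md$compartment == compartment])
  dyads <- stats::setNames(
    ch$metadata$sample_id[match(mom$metadata$subject_id,
                                ch$metadata$subject_id)],
    mom$metadata$sample_id)
  list(mom = mom, child = ch, dyads = dyads)
}

# -- oracles ----------------------------------------------------------------

# Fisher two-sided p by exhaustive fixed-margin enumeration with choose()
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  m <- a + b    # mother-present margin
  k <- a + c    # child-present margin
  a_range <- max(0, m + k - n):min(m, k)
  prob <- choose(m, a_range) * choose(n - m, k - a_range) / choose(n, k)
  obs <- prob[match(a, a_range)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# unweighted UniFrac by per-branch enumeration using phangorn descendants
oracle_unweighted_unifrac <- function(tree, present_a, present_b) {
  n_tip <- length(tree$tip.label)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
    in_a <- any(tips %in% present_a)
    in_b <- any(tips %in% present_b)
    if (in_a || in_b) den <- den + tree$edge.length[e]
    if (xor(in_a, in_b)) num <- num + tree$edge.length[e]
  }
  num / den
}

# one-factor PERMANOVA pieces from raw within/between squared distances
oracle_permanova_ss <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  k <- nlevels(groups)
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(ss_total = ss_total, ss_between = ss_between, ss_within = ss_within,
       f = f, r2 = ss_between / ss_total)
}

# exact paired signed-rank two-sided p by enumeration over sign vectors
# (assumes no zero and no tied |differences|)
oracle_signed_rank_p <- function(diffs) {
  n <- length(diffs)
  ranks <- rank(abs(diffs))
  v_obs <- sum(ranks[diffs > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(ranks[unlist(s)]))
  lo <- mean(v_all <= v_obs)
  hi <- mean(v_all >= v_obs)
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}
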