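#' Per-OTU presence/absence transfer scan
#'
#' For one child compartment, tests every eligible OTU for mother-to-child
#' transfer: over the n dyads, presence (count > 0) in the mother's vaginal
#' birth sample is crossed with presence in her child's sample in a 2x2
#' table, summarised by its odds ratio and a two-sided Fisher exact
#' p-value. Only OTUs whose presence count lies strictly between 0 and n on
#' *both* margins (the mother side and the child side) are informative and
#' enter the scan.
#'
#' The odds ratio is the sample (cross-product) OR; when any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells so downstream
#' log-odds weights stay finite. The two-sided p sums hypergeometric
#' probabilities not exceeding that of the observed table (the convention
#' of standard Fisher-test implementations).
#'
#' @param vaginal_birth a [count_table()] of the mothers' vaginal birth
#'   samples, one per dyad.
#' @param child a [count_table()] of one child compartment, one sample per
#'   dyad.
#' @param dyads named character vector mapping mother sample ids to child
#'   sample ids (names = vaginal birth sample ids).
#' @return a `transfer_scan` data.frame with one row per eligible OTU:
#'   `otu`, cells `a` (mother+ child+), `b` (mother+ child-), `c`
#'   (mother- child+), `d` (mother- child-), `or`, `p`, `carriers` (number
#'   of children carrying the OTU). Attributes: `n` (dyads), `compartment`.
#' @export
transfer_scan <- function(vaginal_birth, child, dyads) {
  ctx <- transfer_context(vaginal_birth, child, dyads)
  scan_from_context(ctx, seq_len(ctx$n))
}

# Validate inputs and precompute everything reused across permutations:
# presence matrices for eligible OTUs and, per OTU, the Fisher p and
# log-OR as a function of the concordant cell a (margins are fixed under
# permutation of the child assignment).
transfer_context <- function(vaginal_birth, child, dyads) {
  if (is.null(names(dyads))) stop("dyads must map mother sample ids to child sample ids")
  if (anyDuplicated(names(dyads)) || anyDuplicated(dyads)) {
    stop("duplicate samples in dyad map")
  }
  miss_m <- setdiff(names(dyads), sample_ids(vaginal_birth))
  if (length(miss_m)) stop("unmatched mother sample: ", miss_m[1L])
  miss_c <- setdiff(dyads, sample_ids(child))
  if (length(miss_c)) stop("unmatched child sample: ", miss_c[1L])
  n <- length(dyads)
  if (n < 3) stop("need >= 3 dyads")
  if (!identical(sort(otu_ids(vaginal_birth)), sort(otu_ids(child)))) {
    stop("mother and child tables must share the OTU universe")
  }
  mom <- vaginal_birth$counts[, names(dyads), drop = FALSE] > 0
  kid <- child$counts[otu_ids(vaginal_birth), dyads, drop = FALSE] > 0
  m_marg <- rowSums(mom)
  c_marg <- rowSums(kid)
  eligible <- m_marg > 0 & m_marg < n & c_marg > 0 & c_marg < n
  mom <- mom[eligible, , drop = FALSE]
  kid <- kid[eligible, , drop = FALSE]
  m_marg <- m_marg[eligible]
  c_marg <- c_marg[eligible]
  n_otu <- sum(eligible)
  # per-OTU lookup vectors indexed by a + 1 (a = 0..n)
  p_lut <- matrix(NA_real_, n + 1L, n_otu)
  lor_lut <- matrix(NA_real_, n + 1L, n_otu)
  key <- paste(m_marg, c_marg)
  for (k in unique(key)) {
    idx <- which(key == k)
    fm <- fisher_margin_tables(m_marg[idx[1L]], c_marg[idx[1L]], n)
    p_lut[fm$a_range + 1L, idx] <- fm$p
    lor_lut[fm$a_range + 1L, idx] <- fm$lor
  }
  list(mom = mom, kid = kid, n = n, n_otu = n_otu,
       m_marg = m_marg, c_marg = c_marg,
       p_lut = p_lut, lor_lut = lor_lut,
       otus = rownames(mom),
       compartment = unique(child$metadata$compartment))
}

# For fixed margins (m mother-present, cc child-present, n dyads): the
# two-sided Fisher p and the (Haldane-corrected where a cell is zero) log
# odds ratio for every attainable concordant cell a. The two-sided rule
# sums hypergeometric probabilities <= the observed one, with the standard
# (1 + 1e-7) relative slack against floating-point ties.
fisher_margin_tables <- function(m, cc, n) {
  a_range <- max(0L, m + cc - n):min(m, cc)
  dens <- stats::dhyper(a_range, m, n - m, cc)
  pv <- vapply(seq_along(a_range), function(r) {
    sum(dens[dens <= dens[r] * (1 + 1e-7)])
  }, 1)
  lor <- vapply(a_range, function(a) {
    b <- m - a; cl <- cc - a; dd <- n - m - cc + a
    if (a == 0 || b == 0 || cl == 0 || dd == 0) {
      log(((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cl + 0.5)))
    } else {
      log((a * dd) / (b * cl))
    }
  }, 1)
  list(a_range = a_range, p = pmin(pv, 1), lor = lor)
}

# Single 2x2 table (a = mother+child+, b = mother+child-, c = mother-child+,
# d = neither): two-sided Fisher p and sample OR via the same machinery the
# scan uses.
fisher_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  fm <- fisher_margin_tables(a + b, a + c, n)
  i <- match(a, fm$a_range)
  list(p = fm$p[i], or = exp(fm$lor[i]))
}

# Build the scan table for a given child permutation (indices into dyads).
scan_from_context <- function(ctx, perm) {
  if (ctx$n_otu == 0) {
    out <- data.frame(otu = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), or = numeric(0),
                      p = numeric(0), carriers = integer(0))
  } else {
    a <- as.integer(rowSums(ctx$mom & ctx$kid[, perm, drop = FALSE]))
    sel <- cbind(a + 1L, seq_len(ctx$n_otu))
    out <- data.frame(
      otu = ctx$otus, a = a, b = as.integer(ctx$m_marg - a),
      c = as.integer(ctx$c_marg - a),
      d = as.integer(ctx$n - ctx$m_marg - ctx$c_marg + a),
      or = exp(ctx$lor_lut[sel]), p = ctx$p_lut[sel],
      carriers = as.integer(ctx$c_marg), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  structure(out, n = ctx$n, compartment = ctx$compartment,
            class = c("transfer_scan", "data.frame"))
}

#' Weighted ratio of positive to negative transfer associations
#'
#' The enrichment statistic summarising a transfer scan:
#' \deqn{WR = \frac{\sum_{i: OR_i > 1} \log(OR_i)\,\log(p_i)}
#'                 {\sum_{i: OR_i < 1} -\log(OR_i)\,\log(p_i)}}
#' with natural logs. OTUs with OR exactly 1 contribute to neither sum and
#' OTUs with p = 1 carry zero weight. Both sums are negative, so WR is
#' positive; under no mother-child association its expectation is 1, and
#' values above 1 indicate enrichment of positive (OR > 1) associations.
#' Because WR is a ratio of sums of log-products, its value does not depend
#' on the (common) log base.
#'
#' @param scan a `transfer_scan` (or any data.frame with columns `or`, `p`).
#' @return the WR value; `Inf` when only positive associations carry
#'   weight, `0` when only negative ones do, `NaN` when neither side does.
#' @export
weighted_ratio <- function(scan) {
  if (nrow(scan) == 0) stop("empty transfer scan")
  wr_from_parts(log(scan$or), log(scan$p))
}

wr_from_parts <- function(lor, lp) {
  num <- sum(lor[lor > 0] * lp[lor > 0])
  den <- sum(-lor[lor < 0] * lp[lor < 0])
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Permutation test of the weighted ratio
#'
#' Builds the null distribution of WR by scrambling which child belongs to
#' which mother: each of the `B` draws applies a uniformly random
#' permutation (identity allowed) to the child assignment, rebuilds every
#' OTU's 2x2 table and recomputes WR. The eligibility set is fixed across
#' draws because both margins are invariant under permutation of the child
#' labels. One-sided upper-tail p: `(1 + #\{WR_null >= WR_obs\}) / (B + 1)`;
#' an infinite observed WR beats every finite null draw, and NaN nulls
#' (no weighted OTU on either side) never count as exceeding.
#'
#' @inheritParams transfer_scan
#' @param B number of permutations (default 999, minimum 19).
#' @param seed integer seed.
#' @return a `wr_test` list: `wr` (observed), `null` (length-B vector),
#'   `p`, `B`, `seed`, `n_otus` (eligible OTUs), `scan` (the observed
#'   `transfer_scan`).
#' @export
wr_permutation_test <- function(vaginal_birth, child, dyads, B = 999, seed = 1) {
  stopifnot(B >= 19)
  ctx <- transfer_context(vaginal_birth, child, dyads)
  obs_scan <- scan_from_context(ctx, seq_len(ctx$n))
  obs <- weighted_ratio(obs_scan)
  set.seed(seed)
  null <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample.int(ctx$n)
    a <- as.integer(rowSums(ctx$mom & ctx$kid[, perm, drop = FALSE]))
    sel <- cbind(a + 1L, seq_len(ctx$n_otu))
    null[b] <- wr_from_parts(ctx$lor_lut[sel], log(ctx$p_lut[sel]))
  }
  if (is.nan(obs)) {
    warning("observed WR is undefined (no weighted OTU on either side)")
    p <- NA_real_
  } else {
    exceed <- if (is.infinite(obs)) {
      sum(is.infinite(null) & null > 0)
    } else {
      sum(!is.nan(null) & null >= obs)
    }
    p <- (1 + exceed) / (B + 1)
  }
  structure(list(wr = obs, null = null, p = p, B = B, seed = seed,
                 n_otus = ctx$n_otu, scan = obs_scan),
            class = "wr_test")
}

#' @export
print.wr_test <- function(x, ...) {
  cat(sprintf("WR enrichment test: WR = %.3f, p = %.4g (B = %d, %d OTUs)\n",
              x$wr, x$p, x$B, x$n_otus))
  invisible(x)
}

#' Maternal abundance as a descriptor of transfer odds
#'
#' Spearman correlation between each eligible OTU's mean relative abundance
#' in the vaginal birth samples and its log odds of transfer.
#'
#' @param scan a `transfer_scan`.
#' @param vaginal_birth a `composition_table` of the vaginal birth samples
#'   containing every scanned OTU.
#' @return list with `rho` and (two-sided) `p`.
#' @export
abundance_odds_correlation <- function(scan, vaginal_birth) {
  if (nrow(scan) < 4) stop("need >= 4 scanned OTUs")
  miss <- setdiff(scan$otu, otu_ids(vaginal_birth))
  if (length(miss)) stop("scanned OTU missing from composition table: ", miss[1L])
  mean_ab <- rowMeans(vaginal_birth$counts[scan$otu, , drop = FALSE])
  ct <- suppressWarnings(
    stats::cor.test(mean_ab, log(scan$or), method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Phylogenetic signal in the transfer odds
#'
#' Mantel-style association between phylogenetic placement and transfer
#' odds: the Spearman correlation between the patristic distances of the
#' scanned OTUs and the pairwise absolute differences of their log odds
#' ratios, squared to an R^2, with significance from leaf-label
#' permutations of the log-odds vector.
#'
#' @param scan a `transfer_scan` whose OTUs are all leaves of `tree`.
#' @param tree rooted `phylo`.
#' @param B permutations (default 999).
#' @param seed integer seed.
#' @return list with `r2`, `p`, and the underlying Mantel correlation `r`.
#' @export
phylo_signal_of_transfer <- function(scan, tree, B = 999, seed = 1) {
  miss <- setdiff(scan$otu, tree$tip.label)
  if (length(miss)) stop("OTU missing from tree: ", miss[1L])
  if (nrow(scan) < 4) stop("need >= 4 scanned OTUs")
  pat <- ape::cophenetic.phylo(tree)[scan$otu, scan$otu]
  lor <- log(scan$or)
  lower <- lower.tri(pat)
  pd <- pat[lower]
  stat <- function(v) {
    dv <- abs(outer(v, v, "-"))[lower]
    if (stats::sd(dv) == 0 || stats::sd(pd) == 0) return(0)
    stats::cor(pd, dv, method = "spearman")
  }
  r_obs <- stat(lor)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    r_null <- stat(sample(lor))
    if (r_null >= r_obs) exceed <- exceed + 1L
  }
  list(r2 = r_obs^2, r = r_obs, p = (1 + exceed) / (B + 1))
}

#' Dyad beta-diversity permutation test
#'
#' Are matched mother-child pairs compositionally closer than randomly
#' matched pairs? The observed statistic is the mean distance between each
#' mother's vaginal birth sample and her own child's sample; the null
#' redraws the child assignment uniformly at random. One-sided lower-tail
#' p: `(1 + #\{null <= observed\}) / (B + 1)`.
#'
#' @inheritParams transfer_scan
#' @param metric a [beta_distance()] metric.
#' @param tree rooted `phylo` (UniFrac metrics only).
#' @param B permutations (default 999).
#' @param seed integer seed.
#' @return a `dyad_dist_test` list: `metric`, `observed`, `null`, `p`, `B`.
#' @export
dyad_distance_test <- function(vaginal_birth, child, dyads,
                               metric = "jsd", tree = NULL, B = 999, seed = 1) {
  if (is.null(names(dyads))) stop("dyads must be a named map")
  n <- length(dyads)
  if (n < 3) stop("need >= 3 dyads")
  mom <- vaginal_birth$counts[, names(dyads), drop = FALSE]
  kid <- child$counts[otu_ids(vaginal_birth), dyads, drop = FALSE]
  # n x n cross-distance matrix (mother i vs child j); permutation draws
  # then only index into it
  cross <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cross[i, j] <- beta_distance(mom[, i], kid[, j], metric, tree = tree)
    }
  }
  observed <- mean(diag(cross))
  set.seed(seed)
  null <- numeric(B)
  idx <- seq_len(n)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    null[b] <- mean(cross[cbind(idx, perm)])
  }
  p <- (1 + sum(null <= observed)) / (B + 1)
  structure(list(metric = metric, observed = observed, null = null,
                 p = p, B = B), class = "dyad_dist_test")
}

#' Truncate odds ratios for display
#'
#' Clips odds ratios to \[0.01, 100\] for volcano-plot style displays;
#' never used as input to the WR statistic.
#'
#' @param or_value odds ratio(s), > 0 (`Inf` allowed).
#' @return clipped value(s).
#' @export
truncate_or_for_display <- function(or_value) {
  pmin(pmax(or_value, 0.01), 100)
}
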