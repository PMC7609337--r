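# presence-pattern fixture: build mother/child count tables realising given
# 2x2 tables for a set of OTUs, over n dyads
tables_from_pattern <- function(mom_presence, child_presence) {
  n <- ncol(mom_presence)
  filler <- matrix(1, 1, n, dimnames = list("O_fill", NULL))  # keeps depths > 0
  mk <- function(pres) rbind(pres * 5, filler)
  make_dyad_tables(mk(mom_presence), mk(child_presence))
}

pattern <- function(a, b, c, d) {
  # dyad-level presence vectors with the requested 2x2 cells
  mom <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  kid <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  rbind(mom = mom, kid = kid)
}

test_that("transfer scan builds correct 2x2 tables, ORs and Fisher p-values", {
  pat <- pattern(5, 1, 1, 5)
  mom <- matrix(pat["mom", ], 1, dimnames = list("O1", NULL))
  kid <- matrix(pat["kid", ], 1, dimnames = list("O1", NULL))
  fx <- tables_from_pattern(mom, kid)
  scan <- transfer_scan(fx$mom, fx$child, fx$dyads)
  row <- scan[scan$otu == "O1", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(5, 1, 1, 5))
  expect_equal(row$or, 25)
  expect_equal(row$p, oracle_fisher_p(5, 1, 1, 5), tolerance = 1e-12)
  expect_equal(row$carriers, 6L)
  expect_equal(attr(scan, "n"), 12L)
})

test_that("OTUs outside the 1..n-1 margin rule are excluded", {
  n <- 8
  mom <- rbind(O_all = rep(1, n),        # present in every mother
               O_none = rep(0, n),       # absent everywhere
               O_ok = c(1, 1, 1, 0, 0, 0, 0, 1))
  kid <- rbind(O_all = c(1, rep(0, n - 1)),
               O_none = c(1, 1, rep(0, n - 2)),
               O_ok = c(1, 0, 1, 0, 1, 0, 0, 1))
  fx <- tables_from_pattern(mom, kid)
  scan <- transfer_scan(fx$mom, fx$child, fx$dyads)
  expect_equal(scan$otu, "O_ok")
  # the filler OTU (present everywhere) is excluded too
  expect_false("O_fill" %in% scan$otu)
})

test_that("zero cells trigger the Haldane correction on all cells", {
  pat <- pattern(3, 0, 0, 3)
  mom <- matrix(pat["mom", ], 1, dimnames = list("O1", NULL))
  kid <- matrix(pat["kid", ], 1, dimnames = list("O1", NULL))
  fx <- tables_from_pattern(mom, kid)
  scan <- transfer_scan(fx$mom, fx$child, fx$dyads)
  expect_equal(scan$or[scan$otu == "O1"], (3.5 * 3.5) / (0.5 * 0.5))  # 49
})

test_that("Fisher p matches stats::fisher.test on random tables", {
  set.seed(12)
  for (i in 1:50) {
    cells <- rmultinom(1, sample(6:30, 1), rep(0.25, 4))
    ft <- stats::fisher.test(matrix(cells, 2))$p.value
    mine <- vertiseq:::fisher_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(mine, ft, tolerance = 1e-9)
  }
})

test_that("weighted ratio reproduces worked values and edge conventions", {
  mk_scan <- function(or, p) {
    structure(data.frame(otu = sprintf("O%d", seq_along(or)), or = or, p = p),
              class = c("transfer_scan", "data.frame"))
  }
  # mirror symmetry: equal and opposite associations
  expect_equal(weighted_ratio(mk_scan(c(2, 0.5), c(0.1, 0.1))), 1)
  # worked value: (ln10 * ln0.01) / (-ln0.1 * ln0.1) = 2
  expect_equal(weighted_ratio(mk_scan(c(10, 0.1), c(0.01, 0.1))), 2)
  # OR = 1 contributes to neither side; p = 1 carries zero weight
  expect_equal(weighted_ratio(mk_scan(c(10, 1, 0.1), c(0.01, 0.001, 0.1))), 2)
  expect_equal(weighted_ratio(mk_scan(c(10, 5, 0.1), c(0.01, 1, 0.1))), 2)
  # one-sided degeneracies
  expect_identical(weighted_ratio(mk_scan(c(2, 3), c(0.1, 0.2))), Inf)
  expect_identical(weighted_ratio(mk_scan(c(0.2, 0.3), c(0.1, 0.2))), 0)
  expect_true(is.nan(weighted_ratio(mk_scan(1, 0.5))))
  expect_error(weighted_ratio(mk_scan(numeric(0), numeric(0))), "empty")

  # log-base invariance: WR is a ratio of log products
  or <- c(4, 2, 0.3, 0.6); p <- c(0.02, 0.2, 0.05, 0.5)
  wr_base <- function(b) {
    num <- sum(log(or[or > 1], b) * log(p[or > 1], b))
    den <- sum(-log(or[or < 1], b) * log(p[or < 1], b))
    num / den
  }
  expect_equal(weighted_ratio(mk_scan(or, p)), wr_base(10))
  expect_equal(wr_base(exp(1)), wr_base(2))

  # equivariance: OR -> 1/OR flips WR -> 1/WR
  expect_equal(weighted_ratio(mk_scan(1 / or, p)),
               1 / weighted_ratio(mk_scan(or, p)))
})

test_that("WR permutation test is seeded, well-calibrated in form, and fast-path consistent", {
  coh <- small_cohort(seed = 31, n_dyads = 16, n_otus = 120)
  dy <- cohort_dyads(coh, "feces")
  res1 <- wr_permutation_test(dy$mom, dy$child, dy$dyads, B = 49, seed = 5)
  res2 <- wr_permutation_test(dy$mom, dy$child, dy$dyads, B = 49, seed = 5)
  expect_identical(res1$null, res2$null)
  expect_equal(res1$p, (1 + sum(res1$null >= res1$wr)) / 50)
  expect_gt(res1$p, 0); expect_lte(res1$p, 1)
  # observed WR from the context fast path equals the plain scan
  expect_equal(res1$wr, weighted_ratio(transfer_scan(dy$mom, dy$child, dy$dyads)))
  # eligibility is permutation-invariant: same OTU set in a shuffled pairing
  shuffled <- stats::setNames(sample(dy$dyads), names(dy$dyads))
  scan_shuf <- transfer_scan(dy$mom, dy$child, shuffled)
  expect_setequal(scan_shuf$otu,
                  transfer_scan(dy$mom, dy$child, dy$dyads)$otu)
})

test_that("permutation null recomputation agrees with explicit re-scan", {
  coh <- small_cohort(seed = 57, n_dyads = 8, n_otus = 120)
  dy <- cohort_dyads(coh, "feces")
  set.seed(99); perm <- sample.int(8)
  permuted_dyads <- stats::setNames(dy$dyads[perm], names(dy$dyads))
  direct <- weighted_ratio(transfer_scan(dy$mom, dy$child, permuted_dyads))
  ctx <- vertiseq:::transfer_context(dy$mom, dy$child, dy$dyads)
  a <- as.integer(rowSums(ctx$mom & ctx$kid[, perm, drop = FALSE]))
  sel <- cbind(a + 1L, seq_len(ctx$n_otu))
  fast <- vertiseq:::wr_from_parts(ctx$lor_lut[sel], log(ctx$p_lut[sel]))
  expect_equal(fast, direct)
})

test_that("abundance-odds correlation: monotone, tie-robust, null-centred", {
  pat_list <- lapply(1:6, function(i) pattern(6 - i %% 3, 2 + i %% 3, 2, 2))
  mom <- do.call(rbind, lapply(pat_list, function(p) p["mom", ]))
  kid <- do.call(rbind, lapply(pat_list, function(p) p["kid", ]))
  rownames(mom) <- rownames(kid) <- paste0("O", 1:6)
  n <- ncol(mom)
  # counts = presence * weight, so mean maternal abundance rises with index
  mom_counts <- mom * matrix(2^(1:6), 6, n)
  fx <- make_dyad_tables(rbind(mom_counts, O_fill = rep(1, n)),
                         rbind(kid * 5, O_fill = rep(1, n)))
  scan <- transfer_scan(fx$mom, fx$child, fx$dyads)
  comp <- relative_abundance(fx$mom)
  res <- abundance_odds_correlation(scan, comp)
  expect_true(abs(res$rho) <= 1)
  expect_true(res$p > 0 && res$p <= 1)
  # perfectly decreasing relation gives rho = -1
  fake <- scan
  ab <- rowMeans(comp$counts[scan$otu, , drop = FALSE])
  fake$or <- exp(-rank(ab))
  expect_equal(abundance_odds_correlation(fake, comp)$rho, -1)
  expect_error(abundance_odds_correlation(scan[1:3, ], comp), "4 scanned")

  # null: abundance independent of OR over replicates
  set.seed(8)
  rhos <- vapply(1:200, function(i) {
    fake$or <- exp(rnorm(nrow(fake)))
    abundance_odds_correlation(fake, comp)$rho
  }, 1)
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("phylogenetic signal: degenerate, clustered and shift-invariant cases", {
  # two deep clades of six shallow leaves each: within-clade patristic
  # distances are far below the between-clade ones
  tr <- ape::read.tree(text = paste0(
    "(((A1:0.1,A2:0.1):0.1,(A3:0.1,A4:0.1):0.1,(A5:0.1,A6:0.1):0.1):1,",
    "((B1:0.1,B2:0.1):0.1,(B3:0.1,B4:0.1):0.1,(B5:0.1,B6:0.1):0.1):1):0;"))
  mk_scan <- function(or) {
    structure(data.frame(otu = tr$tip.label, or = or,
                         p = rep(0.05, 12)),
              class = c("transfer_scan", "data.frame"))
  }
  # constant log OR: no signal
  res0 <- phylo_signal_of_transfer(mk_scan(rep(2, 12)), tr, B = 99, seed = 1)
  expect_equal(res0$r2, 0)

  # OR clustered perfectly by clade: |delta log OR| is a monotone function
  # of patristic separation, so the Mantel correlation is 1
  or <- ifelse(startsWith(tr$tip.label, "A"), 10, 0.1)
  res1 <- phylo_signal_of_transfer(mk_scan(or), tr, B = 199, seed = 2)
  expect_gt(res1$r2, 0.9)
  expect_lt(res1$p, 0.05)

  # invariant to adding a constant to all log ORs
  res2 <- phylo_signal_of_transfer(mk_scan(or * 7), tr, B = 199, seed = 2)
  expect_equal(res2$r2, res1$r2)
  expect_equal(res2$p, res1$p)

  expect_error(phylo_signal_of_transfer(
    structure(data.frame(otu = "nope", or = 2, p = 0.1),
              class = c("transfer_scan", "data.frame")), tr), "missing")
})

test_that("dyad distance test: cloned children give the minimal p", {
  set.seed(3)
  n <- 8
  # sparse baseline + a private marker OTU per mother: presence sets (and
  # hence all metrics) differ between any two mothers
  mom_counts <- matrix(rpois(20 * n, 1), 20, n,
                       dimnames = list(paste0("O", 1:20), NULL))
  mom_counts <- mom_counts + diag(20)[, 1:n] * 50
  fx <- make_dyad_tables(mom_counts, mom_counts)   # children cloned
  for (m in c("jaccard", "bray_curtis", "jsd")) {
    res <- dyad_distance_test(fx$mom, fx$child, fx$dyads, metric = m,
                              B = 99, seed = 11)
    expect_equal(res$observed, 0)
    expect_equal(res$p, 1 / 100)
  }
  # relabelling invariance of the observed statistic
  perm <- sample(n)
  res_a <- dyad_distance_test(fx$mom, fx$child, fx$dyads, metric = "jsd",
                              B = 19, seed = 1)
  res_b <- dyad_distance_test(fx$mom, fx$child, fx$dyads[perm], metric = "jsd",
                              B = 19, seed = 1)
  expect_equal(res_a$observed, res_b$observed)
})

test_that("display truncation clips odds ratios to [0.01, 100]", {
  expect_equal(truncate_or_for_display(0.001), 0.01)
  expect_equal(truncate_or_for_display(250), 100)
  expect_equal(truncate_or_for_display(3.7), 3.7)
  expect_equal(truncate_or_for_display(Inf), 100)
  expect_equal(truncate_or_for_display(c(0.005, 1, 1e6)), c(0.01, 1, 100))
})
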