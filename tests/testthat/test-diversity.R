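tiny_tree <- function(newick) {
  ape::read.tree(text = newick)
}

test_that("alpha diversity matches closed-form values", {
  expect_equal(alpha_diversity(c(10, 10, 10, 10), "shannon"), log(4))
  expect_equal(alpha_diversity(c(5, 0, 0), "shannon"), 0)
  expect_equal(alpha_diversity(c(5, 0, 0), "richness"), 1)
  expect_error(alpha_diversity(c(0, 0), "shannon"), "zero depth")

  tr <- tiny_tree("(A:1,B:1):0;")
  expect_equal(alpha_diversity(c(A = 3, B = 0), "faith_pd", tree = tr), 1)
  expect_equal(alpha_diversity(c(A = 3, B = 2), "faith_pd", tree = tr), 2)
  expect_error(alpha_diversity(c(A = 1, Z = 1), "faith_pd", tree = tr), "Z")
})

test_that("shannon is bounded by log richness; faith PD is monotone", {
  set.seed(42)
  tr <- simulate_tree(12, seed = 5)$tree
  for (i in 1:25) {
    x <- rpois(12, 2)
    if (sum(x) == 0) x[1] <- 1
    names(x) <- tr$tip.label
    sh <- alpha_diversity(x, "shannon")
    expect_lte(sh, log(alpha_diversity(x, "richness")) + 1e-12)
    pd <- alpha_diversity(x, "faith_pd", tree = tr)
    y <- x
    absent <- which(y == 0)
    if (length(absent)) {
      y[absent[1]] <- 1
      expect_gte(alpha_diversity(y, "faith_pd", tree = tr), pd)
    }
  }
  # uniform sample attains the bound
  u <- stats::setNames(rep(7, 12), tr$tip.label)
  expect_equal(alpha_diversity(u, "shannon"), log(12))
})

test_that("faith PD agrees with picante's rooted PD", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(20, seed = 8)$tree
  set.seed(1)
  mat <- matrix(rpois(5 * 20, 1), 5, 20, dimnames = list(NULL, tr$tip.label))
  mat[rowSums(mat) == 0, 1] <- 1
  mine <- apply(mat, 1, alpha_diversity, metric = "faith_pd", tree = tr)
  ref <- picante::pd(mat, tr, include.root = TRUE)$PD
  expect_equal(unname(mine), ref, tolerance = 1e-10)
})

test_that("beta distances satisfy identity, symmetry and range", {
  tr <- simulate_tree(10, seed = 2)$tree
  set.seed(7)
  metrics <- c("unweighted_unifrac", "weighted_unifrac", "jaccard",
               "bray_curtis", "jsd")
  for (i in 1:10) {
    a <- stats::setNames(rpois(10, 2), tr$tip.label)
    b <- stats::setNames(rpois(10, 2), tr$tip.label)
    if (sum(a) == 0) a[1] <- 1
    if (sum(b) == 0) b[2] <- 1
    for (m in metrics) {
      expect_equal(beta_distance(a, a, m, tree = tr), 0)
      dab <- beta_distance(a, b, m, tree = tr)
      expect_equal(dab, beta_distance(b, a, m, tree = tr))
      expect_gte(dab, 0)
      if (m %in% c("jaccard", "bray_curtis", "unweighted_unifrac",
                   "weighted_unifrac")) {
        expect_lte(dab, 1)
      }
    }
  }
  expect_error(beta_distance(c(A = 1), c(A = 1), "unweighted_unifrac"), "tree")
})

test_that("unweighted UniFrac matches branch-by-branch enumeration", {
  # disjoint samples on a two-leaf star: all branch length unshared
  tr <- tiny_tree("(A:1,B:1):0;")
  expect_equal(beta_distance(c(A = 1, B = 0), c(A = 0, B = 1),
                             "unweighted_unifrac", tree = tr), 1)
  # worked 4-branch example: sample1 = {A}, sample2 = {A, C}
  tr2 <- tiny_tree("((A:1,B:1):1,C:2):0;")
  # branches: A(1, shared), B(1, absent both), inner(1, shared), C(2, only s2)
  expect_equal(beta_distance(c(A = 5, B = 0, C = 0), c(A = 1, B = 0, C = 2),
                             "unweighted_unifrac", tree = tr2), 2 / 4)
  expect_equal(oracle_unweighted_unifrac(tr2, "A", c("A", "C")), 2 / 4)
})

test_that("UniFrac agrees with phyloseq on random communities", {
  skip_if_not_installed("phyloseq")
  tr <- simulate_tree(15, seed = 3)$tree
  set.seed(5)
  mat <- matrix(rpois(15 * 6, 2), 15, 6,
                dimnames = list(tr$tip.label, paste0("s", 1:6)))
  mat[, colSums(mat) == 0][1] <- 1
  ps <- phyloseq::phyloseq(phyloseq::otu_table(mat, taxa_are_rows = TRUE), tr)
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  mine_u <- vertiseq:::unifrac_matrix(t(mat), tr, weighted = FALSE)
  mine_w <- vertiseq:::unifrac_matrix(t(mat), tr, weighted = TRUE)
  expect_equal(mine_u[rownames(ref_u), colnames(ref_u)], ref_u,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mine_w[rownames(ref_w), colnames(ref_w)], ref_w,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("distance_matrix is the pairwise closure of beta_distance", {
  coh <- small_cohort(seed = 6, n_dyads = 3, n_otus = 15)
  vag <- subset_samples(coh$table, coh$table$metadata$compartment == "vaginal")
  d <- distance_matrix(vag, "bray_curtis")
  expect_equal(attr(d, "metric"), "bray_curtis")
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, ncol(vag$counts)))
  for (i in 1:3) {
    for (j in 5:6) {
      expect_equal(d[i, j],
                   beta_distance(vag$counts[, i], vag$counts[, j], "bray_curtis"))
    }
  }
  # identical samples give an all-zero matrix
  same <- vag
  same$counts[] <- vag$counts[, 1]
  expect_true(all(distance_matrix(same, "jsd") == 0))
  # permutation equivariance
  perm <- rev(seq_len(ncol(vag$counts)))
  d2 <- distance_matrix(subset_samples(vag, perm), "bray_curtis")
  expect_equal(unclass(d2), unclass(d)[perm, perm], ignore_attr = TRUE)
})

test_that("PCoA recovers collinear geometry and conserves the Gram trace", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa_ordination(structure(d, metric = "euclidean"))
  expect_equal(length(ord$eigenvalues), 1L)
  expect_equal(abs(ord$coordinates[, 1]), c(a = 1, b = 0, c = 1))
  expect_equal(ord$prop_explained, 1)

  set.seed(10)
  pts <- matrix(rnorm(8 * 3), 8)
  de <- as.matrix(dist(pts))
  orde <- pcoa_ordination(de)
  # exactness: full coordinates reproduce the distances
  rec <- as.matrix(dist(orde$coordinates))
  expect_equal(unname(rec), unname(de), tolerance = 1e-8)
  # trace identity: sum of positive eigenvalues = trace of centred Gram
  n <- nrow(de)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% de^2 %*% j
  expect_equal(sum(orde$eigenvalues), sum(diag(g)), tolerance = 1e-9)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "3 samples")
})

test_that("sequential PERMANOVA matches direct sums-of-squares arithmetic", {
  # two well-separated triplets in the plane
  set.seed(99)
  pts <- rbind(matrix(rnorm(6, 0), 3), matrix(rnorm(6, 10), 3))
  d <- structure(as.matrix(dist(pts)), metric = "euclidean",
                 dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  grp <- rep(c("x", "y"), each = 3)
  res <- permanova(d, list(group = grp), n_perm = 99, seed = 1)
  oracle <- oracle_permanova_ss(d, grp)
  expect_equal(res$ss[res$term == "group"], oracle$ss_between, tolerance = 1e-9)
  expect_equal(res$f[res$term == "group"], oracle$f, tolerance = 1e-9)
  expect_equal(res$fraction[res$term == "group"], oracle$r2, tolerance = 1e-9)
  # fractions decompose exactly
  expect_equal(sum(res$fraction[res$term != "total"]), 1, tolerance = 1e-9)

  expect_error(permanova(d, list(g = rep("x", 6))), "single level")
  expect_error(permanova(d, list(g = paste0("l", 1:6)), n_perm = 9),
               "more parameters")
})

test_that("PERMANOVA p-values are superuniform under the null", {
  set.seed(77)
  pvals <- vapply(1:150, function(i) {
    pts <- matrix(rnorm(24), 12)
    d <- structure(as.matrix(dist(pts)),
                   dimnames = list(paste0("s", 1:12), paste0("s", 1:12)))
    grp <- sample(rep(c("x", "y"), each = 6))
    permanova(d, list(group = grp), n_perm = 199, seed = i)$p[1]
  }, 1)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(pvals <= 0.05), 0.12)
})

test_that("alpha variance decomposition matches group-mean arithmetic", {
  # 6 subjects x 3 timepoints with fixed additive effects
  subj <- rep(paste0("S", 1:6), each = 3)
  tp <- rep(c("w24", "w36", "birth"), 6)
  subj_eff <- rep(c(0, 1, 2, 3, 4, 5), each = 3)
  tp_eff <- rep(c(0, 0.5, 1), 6)
  set.seed(2)
  y <- subj_eff + tp_eff + rnorm(18, sd = 0.1)
  res <- alpha_variance_decomposition(y, subj, tp)
  # balanced design: sequential SS equal the direct group-mean SS
  ybar <- mean(y)
  ss_subj <- sum(tapply(y, subj, function(v) length(v) * (mean(v) - ybar)^2))
  ss_tp <- sum(tapply(y, tp, function(v) length(v) * (mean(v) - ybar)^2))
  ss_tot <- sum((y - ybar)^2)
  expect_equal(res$ss[res$term == "subject"], ss_subj, tolerance = 1e-9)
  expect_equal(res$ss[res$term == "timepoint"], ss_tp, tolerance = 1e-9)
  expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
  expect_equal(res$fraction[res$term == "subject"], ss_subj / ss_tot,
               tolerance = 1e-9)

  # values driven by subject only: subject fraction ~ 1
  y2 <- subj_eff + rnorm(18, sd = 1e-6)
  res2 <- alpha_variance_decomposition(y2, subj, tp)
  expect_gt(res2$fraction[res2$term == "subject"], 0.999)

  # constant values: residual carries fraction 1
  res3 <- alpha_variance_decomposition(rep(2, 18), subj, tp)
  expect_equal(res3$fraction[res3$term == "residual"], 1)
  expect_error(alpha_variance_decomposition(y, subj, subj), "confounded")
})

test_that("axis-factor R2 is saturated at one point per level and null-calibrated", {
  set.seed(30)
  pts <- matrix(rnorm(20), 10)
  d <- structure(as.matrix(dist(pts)),
                 dimnames = list(paste0("s", 1:10), paste0("s", 1:10)))
  ord <- pcoa_ordination(d)
  sat <- coordinate_factor_r2(ord, 1, paste0("lvl", 1:10))
  expect_equal(sat$r2, 1)
  expect_error(coordinate_factor_r2(ord, 1, rep("a", 10)), "2 levels")

  # E[R2] under an independent factor with k levels is (k-1)/(n-1)
  r2s <- vapply(1:300, function(i) {
    set.seed(1000 + i)
    fac <- sample(rep(c("a", "b"), each = 5))
    coordinate_factor_r2(ord, 1, fac)$r2
  }, 1)
  expect_lt(abs(mean(r2s) - 1 / 9), 0.02)
})
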