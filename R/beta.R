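#' Between-sample (beta) distances
#'
#' Pairwise community distances between two count vectors over the same OTU
#' universe. Metrics:
#' \describe{
#'   \item{unweighted_unifrac}{fraction of total branch length (over branches
#'     leading to either sample's taxa) that leads to taxa of exactly one
#'     sample; presence/absence, tree required.}
#'   \item{weighted_unifrac}{normalised abundance-weighted UniFrac:
#'     `sum(l_b |pA_b - pB_b|) / sum(l_b (pA_b + pB_b))` over branches `b`,
#'     where `p_b` is the fraction of a sample's reads below branch `b`;
#'     values in \[0, 1\].}
#'   \item{jaccard}{1 - |intersection| / |union| of presence sets.}
#'   \item{bray_curtis}{`sum |x - y| / sum (x + y)` on counts.}
#'   \item{jsd}{Jensen-Shannon divergence of the relative abundance vectors,
#'     natural log (finite without pseudocounts; `0 ln 0 = 0`).}
#' }
#'
#' @param a,b named numeric count vectors (same OTU universe; names required
#'   for the UniFrac metrics).
#' @param metric one of the metrics above.
#' @param tree rooted `phylo` containing all observed OTUs (UniFrac only).
#' @return a single distance.
#' @export
beta_distance <- function(a, b,
                          metric = c("unweighted_unifrac", "weighted_unifrac",
                                     "jaccard", "bray_curtis", "jsd"),
                          tree = NULL) {
  metric <- match.arg(metric)
  if (sum(a) == 0 && sum(b) == 0) stop("both samples are empty")
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop(metric, " requires a tree")
    m <- rbind(a, b)
    if (is.null(colnames(m))) stop("UniFrac requires named count vectors")
    d <- unifrac_matrix(m, tree, weighted = metric == "weighted_unifrac")
    return(d[1, 2])
  }
  switch(metric,
    jaccard = {
      pa <- a > 0; pb <- b > 0
      1 - sum(pa & pb) / sum(pa | pb)
    },
    bray_curtis = sum(abs(a - b)) / sum(a + b),
    jsd = jsd_pair(a / sum(a), b / sum(b))
  )
}

jsd_pair <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log(x[i] / y[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# UniFrac over the rows of a samples x OTU matrix; returns a dense
# symmetric matrix. One edge-incidence computation serves all pairs.
unifrac_matrix <- function(mat, tree, weighted) {
  obs <- colnames(mat)[colSums(mat) > 0]
  miss <- setdiff(obs, tree$tip.label)
  if (length(miss)) stop("observed OTU missing from tree: ", miss[1L])
  desc <- edge_leaf_incidence(tree)
  len <- tree$edge.length
  n <- nrow(mat)
  # per-sample branch mass: fraction of reads below each edge
  prop <- mat / rowSums(mat)
  # pad to tree tip set (absent tips contribute zero mass)
  full <- matrix(0, n, length(tree$tip.label),
                 dimnames = list(rownames(mat), tree$tip.label))
  common <- intersect(colnames(mat), tree$tip.label)
  full[, common] <- prop[, common, drop = FALSE]
  branch_mass <- full %*% t(desc)          # n x n_edge
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bi <- branch_mass[i, ]; bj <- branch_mass[j, ]
      if (weighted) {
        num <- sum(len * abs(bi - bj))
        den <- sum(len * (bi + bj))
      } else {
        ai <- bi > 0; aj <- bj > 0
        num <- sum(len[xor(ai, aj)])
        den <- sum(len[ai | aj])
      }
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  d
}

#' All-pairs distance matrix for a count table
#'
#' @param table a [count_table()] (or `composition_table` for abundance
#'   metrics) with at least 2 samples.
#' @param metric see [beta_distance()].
#' @param tree rooted `phylo` (UniFrac metrics only).
#' @return a `distance_matrix`: square symmetric matrix with sample ids as
#'   dimnames and attribute `"metric"`.
#' @export
distance_matrix <- function(table, metric = "bray_curtis", tree = NULL) {
  metric <- match.arg(metric, c("unweighted_unifrac", "weighted_unifrac",
                                "jaccard", "bray_curtis", "jsd"))
  if (ncol(table$counts) < 2) stop("need >= 2 samples")
  m <- t(table$counts)
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop(metric, " requires a tree")
    d <- unifrac_matrix(m, tree, weighted = metric == "weighted_unifrac")
  } else {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- beta_distance(m[i, ], m[j, ], metric)
      }
    }
  }
  structure(d, metric = metric, class = c("distance_matrix", "matrix"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centred squared distance matrix
#' `-0.5 * J D^2 J`. Axes with eigenvalues below `tol * max(eigenvalue)`
#' (and all negative axes) are dropped; the proportion explained is taken
#' over the positive eigenvalues.
#'
#' @param d a `distance_matrix` (or any symmetric matrix with zero diagonal).
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return an `ordination`: list with `coordinates` (samples x axes,
#'   columns `PCo1`, `PCo2`, ...), `eigenvalues` (positive, descending) and
#'   `prop_explained`.
#' @export
pcoa_ordination <- function(d, tol = 1e-10) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; routine for
  # semi-metric distances (Bray-Curtis, JSD), so not propagated
  mds <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ev <- mds$eig
  pos <- which(ev > tol * max(ev, 0) & ev > 0)
  if (!length(pos)) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
    return(structure(list(coordinates = coords, eigenvalues = numeric(0),
                          prop_explained = numeric(0)), class = "ordination"))
  }
  coords <- mds$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(d)
  eig <- ev[pos]
  structure(list(coordinates = coords, eigenvalues = eig,
                 prop_explained = eig / sum(ev[ev > 0])),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d samples, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$prop_explained)) {
    cat("proportion explained:",
        paste0(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 5)),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sequential PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA with sequential (order-dependent) sums
#' of squares, as implemented by [vegan::adonis2()] with `by = "terms"`:
#' pseudo-F per term and permutation p-values under free row permutation,
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @param d a `distance_matrix`.
#' @param terms named list (or data.frame) of factors, one entry per model
#'   term, in the order the sequential decomposition should use.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return a `variance_decomposition` data.frame: `term`, `df`, `ss`,
#'   `fraction` (R^2), `f`, `p`, with residual and total rows.
#' @export
permanova <- function(d, terms, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 1)
  df <- as.data.frame(terms, stringsAsFactors = FALSE)
  df[] <- lapply(df, function(v) if (is.numeric(v)) v else factor(v))
  for (nm in names(df)) {
    if (length(unique(df[[nm]])) < 2) stop("term '", nm, "' has a single level")
  }
  n <- nrow(as.matrix(d))
  n_par <- sum(vapply(df, function(v) {
    if (is.factor(v)) nlevels(v) - 1L else 1L
  }, 1L)) + 1L
  if (n_par >= n) stop("more parameters than samples")
  dd <- stats::as.dist(as.matrix(d))
  fml <- stats::as.formula(paste("dd ~", paste(names(df), collapse = " + ")))
  set.seed(seed)
  res <- vegan::adonis2(fml, data = df, permutations = n_perm, by = "terms")
  term <- rownames(res)
  term[term == "Residual"] <- "residual"
  term[term == "Total"] <- "total"
  out <- data.frame(term = term, df = res$Df, ss = res$SumOfSqs,
                    fraction = res$R2, f = res$F, p = res$`Pr(>F)`,
                    row.names = NULL)
  class(out) <- c("variance_decomposition", "data.frame")
  out
}
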