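#' Partition OTUs by compartment sharing
#'
#' Classifies every OTU into one of the seven regions of the three-set Venn
#' diagram over the compartments (vaginal, feces, airway): an OTU belongs to
#' a compartment when it has a nonzero count in at least one sample of that
#' compartment. "Ubiquitous" OTUs occupy the triple-overlap region. For each
#' region the fraction of all reads (across every sample of every
#' compartment) carried by that region's OTUs is reported.
#'
#' @param table a [count_table()] containing samples of all three
#'   compartments.
#' @return a `sharing_partition` data.frame: `region` (e.g.
#'   `"vaginal+feces+airway"`), `n_otus`, `read_fraction`, and a list column
#'   `otus` of OTU ids. OTUs absent everywhere are excluded from the
#'   denominator of `n_otus` but carry no reads anyway.
#' @export
compartment_partition <- function(table) {
  comps <- c("vaginal", "feces", "airway")
  miss <- setdiff(comps, unique(table$metadata$compartment))
  if (length(miss)) stop("missing compartment: ", miss[1L])
  present_in <- sapply(comps, function(cp) {
    idx <- table$metadata$compartment == cp
    rowSums(table$counts[, idx, drop = FALSE]) > 0
  })
  observed <- rowSums(present_in) > 0
  total_reads <- sum(table$counts)
  region_key <- apply(present_in, 1, function(z) paste(comps[z], collapse = "+"))
  regions <- c("vaginal", "feces", "airway",
               "vaginal+feces", "vaginal+airway", "feces+airway",
               "vaginal+feces+airway")
  reads_per_otu <- rowSums(table$counts)
  out <- data.frame(region = regions, n_otus = 0L, read_fraction = 0)
  out$otus <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    sel <- observed & region_key == regions[i]
    out$n_otus[i] <- sum(sel)
    out$read_fraction[i] <- sum(reads_per_otu[sel]) / total_reads
    out$otus[[i]] <- otu_ids(table)[sel]
  }
  class(out) <- c("sharing_partition", "data.frame")
  out
}

#' SparCC correlations within one compartment
#'
#' Sparse correlations for compositional data: per inner iteration the
#' observed counts are resampled to fractions via Dirichlet(count + 1)
#' draws; the log-ratio variances `t_ij = var(log(f_i / f_j))` are reduced
#' to basis variances under the sparsity approximation, strongly correlated
#' pairs are iteratively excluded from the linear system, and correlations
#' are recomputed. The reported matrix is the elementwise median across the
#' inner iterations, clipped to \[-1, 1\].
#'
#' @param table a [count_table()] restricted to one compartment, with at
#'   least 4 samples and 4 OTUs.
#' @param n_inner number of Dirichlet resampling iterations (default 20).
#' @param n_exclude maximum pair-exclusion rounds per iteration (default 10).
#' @param exclusion_threshold only pairs with |correlation| above this value
#'   are excluded (default 0.1, the original algorithm's setting).
#' @param seed integer seed.
#' @return symmetric correlation matrix with unit diagonal, OTU ids as
#'   dimnames. OTUs with all-zero counts get zero correlations and a
#'   warning.
#' @export
sparcc_correlation <- function(table, n_inner = 20, n_exclude = 10,
                               exclusion_threshold = 0.1, seed = 1) {
  counts <- t(table$counts)            # samples x OTUs
  if (nrow(counts) < 4) stop("need >= 4 samples")
  if (ncol(counts) < 4) stop("need >= 4 OTUs")
  degenerate <- apply(counts, 2, function(x) all(x == 0) || stats::var(x) == 0)
  if (any(degenerate)) {
    warning("constant OTU(s) across samples; correlations set to 0: ",
            paste(colnames(counts)[degenerate], collapse = ", "))
  }
  use <- which(!degenerate)
  d <- length(use)
  set.seed(seed)
  full <- matrix(0, ncol(counts), ncol(counts),
                 dimnames = list(colnames(counts), colnames(counts)))
  diag(full) <- 1
  if (d < 2) return(full)
  x <- counts[, use, drop = FALSE]
  n <- nrow(x)
  draws <- array(NA_real_, c(d, d, n_inner))
  for (it in seq_len(n_inner)) {
    # Dirichlet(count + 1) fractions per sample
    g <- matrix(stats::rgamma(n * d, shape = x + 1), n, d)
    f <- g / rowSums(g)
    lf <- log(f)
    # log-ratio variance matrix t_ij
    v <- stats::var(lf)
    tij <- outer(diag(v), diag(v), "+") - 2 * v
    draws[, , it] <- sparcc_basis(tij, n_exclude, exclusion_threshold)
  }
  med <- apply(draws, c(1, 2), stats::median)
  med <- pmin(pmax(med, -1), 1)
  diag(med) <- 1
  full[use, use] <- med
  full
}

# Solve the sparsity approximation t_ij ~ w_i + w_j for basis variances w
# over the non-excluded pairs, then correlations; exclude the most
# correlated pair and repeat.
sparcc_basis <- function(tij, n_exclude, exclusion_threshold) {
  d <- nrow(tij)
  included <- matrix(TRUE, d, d)
  diag(included) <- FALSE
  rho <- NULL
  for (round in seq_len(n_exclude + 1L)) {
    deg <- rowSums(included)
    if (any(deg < 1)) break
    # linear system: sum_{j in P_i} t_ij = |P_i| w_i + sum_{j in P_i} w_j
    A <- included * 1
    diag(A) <- deg
    trow <- rowSums(tij * included)
    w <- tryCatch(solve(A, trow), error = function(e) NULL)
    if (is.null(w)) break
    w <- pmax(w, 1e-12)
    denom <- 2 * sqrt(outer(w, w))
    new_rho <- (outer(w, w, "+") - tij) / denom
    diag(new_rho) <- 1
    rho <- new_rho
    if (round > n_exclude) break
    cand <- abs(rho) * included
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    included[idx[1], idx[2]] <- included[idx[2], idx[1]] <- FALSE
  }
  if (is.null(rho)) {
    rho <- diag(d)
  }
  rho
}

#' Merge per-compartment correlations into a co-occurrence edge list
#'
#' For every OTU pair the correlation is the maximum across the
#' compartments in which both OTUs were estimable; pairs with `r` at or
#' below the threshold are pruned (the threshold applies to the signed
#' value, so strong negative correlations are excluded too).
#'
#' @param corr_by_compartment named list of correlation matrices (names are
#'   compartments); OTUs absent from a matrix are treated as not estimable
#'   there.
#' @param threshold prune edges with `r <= threshold` (default 0.2).
#' @return an `edge_list` data.frame: `otu_a`, `otu_b`, `r`, `compartment`
#'   (the argmax compartment), each unordered pair at most once.
#' @export
cooccurrence_edges <- function(corr_by_compartment, threshold = 0.2) {
  if (is.null(names(corr_by_compartment))) {
    stop("corr_by_compartment must be a named list")
  }
  all_otus <- sort(unique(unlist(lapply(corr_by_compartment, rownames))))
  out <- list()
  k <- 0L
  for (i in seq_along(all_otus)) {
    for (j in seq_len(i - 1L)) {
      a <- all_otus[j]; b <- all_otus[i]
      best <- -Inf; best_comp <- NA_character_
      for (cp in names(corr_by_compartment)) {
        m <- corr_by_compartment[[cp]]
        if (a %in% rownames(m) && b %in% rownames(m)) {
          r <- m[a, b]
          if (!is.na(r) && r > best) {
            best <- r; best_comp <- cp
          }
        }
      }
      if (is.finite(best) && best > threshold) {
        k <- k + 1L
        out[[k]] <- data.frame(otu_a = a, otu_b = b, r = best,
                               compartment = best_comp,
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (k) do.call(rbind, out) else
    data.frame(otu_a = character(0), otu_b = character(0),
               r = numeric(0), compartment = character(0))
  class(res) <- c("edge_list", "data.frame")
  res
}

#' OTUs unique to the birth samples
#'
#' Finds OTUs never observed in any week-24 or week-36 vaginal sample but
#' present in at least one birth sample, the subset of those present in at
#' least `min_prevalence` birth samples, and the combined relative
#' abundance these birth-unique OTUs reach per birth sample.
#'
#' @param vaginal a [count_table()] restricted to vaginal samples with all
#'   three timepoints present.
#' @param min_prevalence prevalence cut for the "recurrent" subset
#'   (default 5 birth samples).
#' @return list with `otus` (all birth-unique OTU ids), `prevalent_otus`
#'   (the recurrent subset), `per_sample` (combined relative abundance of
#'   birth-unique OTUs in each birth sample) and `summary` (median and IQR
#'   of those values).
#' @export
birth_unique_otus <- function(vaginal, min_prevalence = 5) {
  md <- vaginal$metadata
  if (!all(c("w24", "w36", "birth") %in% md$timepoint)) {
    stop("need vaginal samples at w24, w36 and birth")
  }
  early <- md$timepoint %in% c("w24", "w36")
  birth <- md$timepoint == "birth"
  if (!any(birth)) stop("no birth samples")
  counts <- vaginal$counts
  in_early <- rowSums(counts[, early, drop = FALSE]) > 0
  birth_prev <- rowSums(counts[, birth, drop = FALSE] > 0)
  unique_sel <- !in_early & birth_prev > 0
  otus <- otu_ids(vaginal)[unique_sel]
  prevalent <- otu_ids(vaginal)[!in_early & birth_prev >= min_prevalence]
  birth_counts <- counts[, birth, drop = FALSE]
  depths <- colSums(birth_counts)
  per_sample <- colSums(birth_counts[unique_sel, , drop = FALSE]) / depths
  qs <- stats::quantile(per_sample, c(0.25, 0.5, 0.75), names = FALSE)
  list(otus = otus, prevalent_otus = prevalent, per_sample = per_sample,
       summary = c(median = qs[2], iqr_lo = qs[1], iqr_hi = qs[3]))
}
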