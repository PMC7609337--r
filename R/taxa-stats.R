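#' Genus-level abundance tests across pregnancy timepoints
#'
#' Selects the `top_n` most abundant genera (by mean relative abundance
#' over all vaginal samples), tests each across the three vaginal
#' timepoints with a Kruskal-Wallis test, adds all pairwise paired Wilcoxon
#' signed-rank contrasts (within mother; mothers missing a timepoint are
#' dropped from that contrast), and controls the false discovery rate with
#' Benjamini-Hochberg within the `top_n` set only.
#'
#' @param comp a `composition_table` of vaginal samples aggregated at genus
#'   level (see [aggregate_by_rank()]), with all three timepoints present.
#' @param top_n number of genera tested (default 15).
#' @return a `taxon_tests` data.frame, one row per genus: per-timepoint
#'   median and IQR, Kruskal-Wallis `p` and BH `q`, a `direction` label
#'   from the timepoint medians, and the three pairwise paired Wilcoxon
#'   p-values.
#' @export
genus_timepoint_tests <- function(comp, top_n = 15) {
  md <- comp$metadata
  tps <- c("w24", "w36", "birth")
  if (!all(tps %in% md$timepoint)) stop("need all three vaginal timepoints")
  mean_ab <- rowMeans(comp$counts)
  top <- utils::head(order(mean_ab, decreasing = TRUE), top_n)
  genera <- otu_ids(comp)[top]
  rows <- lapply(genera, function(g) {
    x <- comp$counts[g, ]
    tp <- factor(md$timepoint, levels = tps)
    kw_p <- if (length(unique(x)) == 1) 1 else stats::kruskal.test(x, tp)$p.value
    meds <- tapply(x, tp, stats::median)
    iqrs <- tapply(x, tp, stats::IQR)
    dir <- if (all(diff(meds) > 0)) "increasing"
           else if (all(diff(meds) < 0)) "decreasing" else "none"
    pw <- pairwise_paired_wilcoxon(x, tp, md$subject_id)
    data.frame(genus = g,
               median_w24 = meds[1], iqr_w24 = iqrs[1],
               median_w36 = meds[2], iqr_w36 = iqrs[2],
               median_birth = meds[3], iqr_birth = iqrs[3],
               test = "kruskal_wallis", p = kw_p,
               direction = dir,
               p_w24_w36 = pw["w24_w36"], p_w36_birth = pw["w36_birth"],
               p_w24_birth = pw["w24_birth"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("genus", "median_w24", "iqr_w24", "median_w36", "iqr_w36",
                 "median_birth", "iqr_birth", "test", "p", "q", "direction",
                 "p_w24_w36", "p_w36_birth", "p_w24_birth")]
  class(out) <- c("taxon_tests", "data.frame")
  out
}

# Paired Wilcoxon signed-rank p for each 2-level timepoint contrast,
# pairing within subject; subjects lacking either timepoint are dropped.
pairwise_paired_wilcoxon <- function(x, tp, subject) {
  contrasts <- list(w24_w36 = c("w24", "w36"),
                    w36_birth = c("w36", "birth"),
                    w24_birth = c("w24", "birth"))
  vapply(contrasts, function(ct) {
    a <- x[tp == ct[1]]; names(a) <- subject[tp == ct[1]]
    b <- x[tp == ct[2]]; names(b) <- subject[tp == ct[2]]
    common <- intersect(names(a), names(b))
    if (length(common) < 3) return(NA_real_)
    diffs <- a[common] - b[common]
    if (all(diffs == 0)) return(1)
    suppressWarnings(
      stats::wilcox.test(a[common], b[common], paired = TRUE,
                         exact = length(common) <= 25)$p.value
    )
  }, 1)
}

#' Log transform for abundance display
#'
#' `log10(x + pseudocount)`; used only when plotting or exporting
#' abundances on a log scale, never in the tests themselves.
#'
#' @param x relative abundance(s), >= 0.
#' @param pseudocount additive constant (default 1e-6).
#' @return log10-transformed values.
#' @export
log_display_transform <- function(x, pseudocount = 1e-6) {
  if (any(x < 0)) stop("negative abundance")
  log10(x + pseudocount)
}

#' Associate a per-mother covariate with the birth microbiome
#'
#' Per-genus Spearman correlations (numeric covariate) or Kruskal-Wallis
#' tests (factor covariate) with BH correction across the tested genera;
#' the same test applied to alpha diversity values; and a single-term
#' PERMANOVA of a beta-diversity matrix on the covariate.
#'
#' @param comp a genus-level `composition_table` of birth samples, one per
#'   mother.
#' @param covariate numeric or factor, aligned with `comp`'s samples.
#' @param alpha_values optional named list/data.frame of per-sample alpha
#'   diversity values to test the same way.
#' @param dist optional `distance_matrix` over the same samples for the
#'   PERMANOVA component.
#' @param n_perm,seed PERMANOVA permutations (999) and seed.
#' @return list with `genus` (data.frame: genus, statistic, p, q), `alpha`
#'   (data.frame or NULL) and `beta` (a `variance_decomposition` or NULL).
#' @export
covariate_association <- function(comp, covariate, alpha_values = NULL,
                                  dist = NULL, n_perm = 999, seed = 1) {
  if (length(unique(covariate)) < 2) stop("constant covariate")
  numeric_cov <- is.numeric(covariate)
  test_one <- function(y) {
    if (numeric_cov) {
      ct <- suppressWarnings(
        stats::cor.test(y, covariate, method = "spearman", exact = FALSE))
      c(statistic = unname(ct$estimate), p = ct$p.value)
    } else {
      kw <- stats::kruskal.test(y, factor(covariate))
      c(statistic = unname(kw$statistic), p = kw$p.value)
    }
  }
  gen <- t(apply(comp$counts, 1, test_one))
  genus_df <- data.frame(genus = otu_ids(comp), statistic = gen[, 1],
                         p = gen[, 2], row.names = NULL)
  genus_df$q <- stats::p.adjust(genus_df$p, method = "BH")
  alpha_df <- NULL
  if (!is.null(alpha_values)) {
    alpha_values <- as.data.frame(alpha_values)
    res <- t(vapply(alpha_values, test_one, c(statistic = 0, p = 0)))
    alpha_df <- data.frame(metric = names(alpha_values), statistic = res[, 1],
                           p = res[, 2], row.names = NULL)
  }
  beta_res <- NULL
  if (!is.null(dist)) {
    beta_res <- permanova(dist, list(covariate = covariate),
                          n_perm = n_perm, seed = seed)
  }
  list(genus = genus_df, alpha = alpha_df, beta = beta_res)
}
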