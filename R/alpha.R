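#' Within-sample (alpha) diversity
#'
#' Computes richness (number of OTUs with nonzero counts), Shannon entropy
#' (natural log, over present taxa) or Faith's phylogenetic diversity (total
#' branch length of the union of root-to-leaf paths of the present taxa, on
#' the supplied rooted tree, root path included).
#'
#' @param sample named numeric vector of counts for one sample (names are
#'   OTU ids; required for `faith_pd`).
#' @param metric `"richness"`, `"shannon"` or `"faith_pd"`.
#' @param tree rooted `phylo`; required for `faith_pd`, whose observed OTUs
#'   must all be leaves of the tree.
#' @return a single number.
#' @export
alpha_diversity <- function(sample, metric = c("richness", "shannon", "faith_pd"),
                            tree = NULL) {
  metric <- match.arg(metric)
  if (sum(sample) <= 0) stop("sample has zero depth")
  present <- sample > 0
  switch(metric,
    richness = sum(present),
    shannon = {
      p <- sample[present] / sum(sample)
      -sum(p * log(p))
    },
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a tree")
      obs <- names(sample)[present]
      if (is.null(obs)) stop("faith_pd requires a named sample vector")
      miss <- setdiff(obs, tree$tip.label)
      if (length(miss)) stop("observed OTU missing from tree: ", miss[1L])
      desc <- edge_leaf_incidence(tree)
      on_path <- rowSums(desc[, obs, drop = FALSE]) > 0
      sum(tree$edge.length[on_path])
    }
  )
}

#' Alpha diversity for every sample of a table
#'
#' @param table a [count_table()].
#' @param metrics character vector of metrics (see [alpha_diversity()]).
#' @param tree rooted `phylo`, needed when `"faith_pd"` is requested.
#' @return data.frame with sample metadata plus one column per metric.
#' @export
alpha_diversity_table <- function(table, metrics = c("richness", "shannon"),
                                  tree = NULL) {
  out <- table$metadata
  desc <- if ("faith_pd" %in% metrics && !is.null(tree)) edge_leaf_incidence(tree)
  for (m in metrics) {
    if (m == "faith_pd") {
      if (is.null(tree)) stop("faith_pd requires a tree")
      miss <- setdiff(otu_ids(table)[rowSums(table$counts) > 0], tree$tip.label)
      if (length(miss)) stop("observed OTU missing from tree: ", miss[1L])
      vals <- apply(table$counts, 2, function(cnt) {
        obs <- rownames(table$counts)[cnt > 0]
        sum(tree$edge.length[rowSums(desc[, obs, drop = FALSE]) > 0])
      })
    } else {
      vals <- apply(table$counts, 2, alpha_diversity, metric = m)
    }
    out[[m]] <- as.numeric(vals)
  }
  out
}

#' Sequential ANOVA decomposition of alpha diversity
#'
#' Splits the variation of a per-sample diversity value into the
#' contribution of the individual subject (mother) and of the sampling
#' timepoint, using sequential (type-I) sums of squares in the order the
#' factors are supplied. With repeated measures of the same women over
#' pregnancy, the subject term captures the individual signature and the
#' timepoint term the systematic succession.
#'
#' @param values numeric vector of alpha diversity values, one per sample.
#' @param subject factor (or coercible) of subject ids.
#' @param timepoint factor of timepoints.
#' @param order either `c("subject", "timepoint")` (default; subject first)
#'   or `c("timepoint", "subject")`.
#' @return a `variance_decomposition` data.frame with one row per term plus
#'   a residual row: `term`, `df`, `ss`, `fraction` (of total SS), `f`, `p`.
#' @export
alpha_variance_decomposition <- function(values, subject, timepoint,
                                         order = c("subject", "timepoint")) {
  subject <- factor(subject)
  timepoint <- factor(timepoint)
  if (nlevels(timepoint) < 2) stop("need >= 2 timepoints")
  if (nlevels(subject) < 2) stop("need >= 2 subjects")
  mm <- stats::model.matrix(~ subject + timepoint)
  if (qr(mm)$rank < ncol(mm)) stop("subject and timepoint are confounded")
  if (stats::var(values) == 0) {
    # degenerate: no variation to decompose; all of it sits in the residual
    terms <- if (identical(order, c("subject", "timepoint"))) {
      c("subject", "timepoint")
    } else c("timepoint", "subject")
    df_of <- c(subject = nlevels(subject) - 1L,
               timepoint = nlevels(timepoint) - 1L)
    out <- data.frame(term = c(terms, "residual"),
                      df = c(unname(df_of[terms]),
                             length(values) - 1L - sum(df_of)),
                      ss = 0, fraction = c(0, 0, 1),
                      f = NA_real_, p = NA_real_)
    class(out) <- c("variance_decomposition", "data.frame")
    return(out)
  }
  dat <- data.frame(y = values, subject = subject, timepoint = timepoint)
  fml <- if (identical(order, c("subject", "timepoint"))) {
    y ~ subject + timepoint
  } else {
    y ~ timepoint + subject
  }
  fit <- stats::aov(fml, data = dat)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  term[term == "Residuals"] <- "residual"
  ss <- tab[["Sum Sq"]]
  total <- sum(ss)
  frac <- if (total > 0) ss / total else rep(0, length(ss))
  out <- data.frame(term = term, df = tab[["Df"]], ss = ss,
                    fraction = frac, f = tab[["F value"]],
                    p = tab[["Pr(>F)"]], row.names = NULL)
  if (total == 0) out$fraction <- c(rep(0, nrow(out) - 1L), 1)
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Variance in one ordination axis explained by a factor
#'
#' One-way ANOVA of the axis scores on the factor: R^2 is the between-group
#' share of the total sum of squares, with the p-value from the F
#' distribution. Used to quantify, e.g., how much of PCo2 is explained by
#' the individual mother.
#'
#' @param ord an `ordination` from [pcoa_ordination()].
#' @param axis axis number (1-based).
#' @param fac factor aligned with the ordination's samples.
#' @return list with `r2` and `p` (`r2 = NA` with `degenerate = TRUE` when
#'   the scores are constant).
#' @export
coordinate_factor_r2 <- function(ord, axis, fac) {
  if (axis > ncol(ord$coordinates)) stop("axis ", axis, " not retained")
  fac <- factor(fac)
  if (nlevels(fac) < 2) stop("factor must have >= 2 levels")
  y <- ord$coordinates[, axis]
  if (stats::var(y) == 0) {
    return(list(r2 = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ fac)
  # a saturated fit (one sample per level) legitimately yields R2 = 1 with
  # no residual df; anova.lm's perfect-fit warning is expected there
  a <- suppressWarnings(stats::anova(fit))
  ssb <- a[["Sum Sq"]][1]
  sst <- sum(a[["Sum Sq"]])
  p <- a[["Pr(>F)"]][1]
  if (is.na(p) && a[["Df"]][2] == 0) p <- NA_real_  # saturated fit
  list(r2 = ssb / sst, p = p, degenerate = FALSE)
}
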