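#' Drop samples below a minimum sequencing depth
#'
#' Samples whose total read count falls below `min_reads` are removed. The
#' boundary is strict: a sample with exactly `min_reads` reads is retained.
#' The default of 2000 reads is the depth threshold commonly applied to
#' V4 16S amplicon data before diversity analysis.
#'
#' @param table a [count_table()].
#' @param min_reads minimum acceptable column sum (default 2000).
#' @param quiet suppress the message listing removed samples.
#' @return the filtered `count_table`; removed sample ids are reported via
#'   `message()` and attached as attribute `"removed_samples"`.
#' @export
filter_low_depth <- function(table, min_reads = 2000, quiet = FALSE) {
  stopifnot(min_reads >= 0)
  depths <- sample_depths(table)
  keep <- depths >= min_reads
  if (!any(keep)) stop("all samples fall below ", min_reads, " reads")
  removed <- names(depths)[!keep]
  if (length(removed) && !quiet) {
    message("filter_low_depth: removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  }
  out <- subset_samples(table, which(keep))
  attr(out, "removed_samples") <- removed
  out
}

#' Rarefy samples to a common depth
#'
#' Each sample is replaced by a uniform subsample of its reads without
#' replacement (one multivariate hypergeometric draw per sample), so all
#' retained samples end at exactly `depth` reads.
#'
#' @param table a [count_table()]; every sample must have at least `depth`
#'   reads (use [filter_low_depth()] first).
#' @param depth target depth per sample.
#' @param seed integer seed; draws are reproducible.
#' @return a `count_table` with all column sums equal to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(depth >= 1)
  depths <- sample_depths(table)
  shallow <- names(depths)[depths < depth]
  if (length(shallow)) {
    stop("sample(s) shallower than ", depth, ": ",
         paste(shallow, collapse = ", "))
  }
  counts <- table$counts
  n_otu <- nrow(counts)
  set.seed(seed)
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (sum(cj) == depth) next
    reads <- rep.int(seq_len(n_otu), cj)
    drawn <- reads[sample.int(length(reads), depth)]
    counts[, j] <- tabulate(drawn, nbins = n_otu)
  }
  out <- table
  out$counts <- counts
  out
}

#' Convert counts to relative abundances
#'
#' @param table a [count_table()] with strictly positive sample depths.
#' @return a `composition_table` (same structure; columns sum to 1).
#' @export
relative_abundance <- function(table) {
  depths <- sample_depths(table)
  if (any(depths == 0)) {
    stop("zero-depth sample: ", names(depths)[depths == 0][1L])
  }
  out <- table
  out$counts <- sweep(table$counts, 2, depths, "/")
  class(out) <- c("composition_table", "count_table")
  out
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Rows are summed within identical lineage prefixes up to `rank`. OTUs
#' unassigned at `rank` are pooled under their deepest assigned ancestor as
#' `unclassified_<ancestor>` (e.g. `unclassified_Enterobacteriaceae`), the
#' labelling convention used for family-only assignments in amplicon
#' surveys.
#'
#' @param table a [count_table()] or `composition_table`.
#' @param tax a [taxonomy()] covering every OTU in `table`.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return a table of the same class with one row per aggregated taxon;
#'   sample sums are unchanged.
#' @export
aggregate_by_rank <- function(table, tax, rank = "genus") {
  rank <- match.arg(rank, tax_ranks())
  miss <- setdiff(otu_ids(table), tax$otu_id)
  if (length(miss)) stop("OTU absent from taxonomy: ", miss[1L])
  tax <- tax[match(otu_ids(table), tax$otu_id), , drop = FALSE]
  ranks <- tax_ranks()
  upto <- ranks[seq_len(match(rank, ranks))]
  labels <- character(nrow(tax))
  for (i in seq_len(nrow(tax))) {
    lin <- as.character(unlist(tax[i, upto]))
    assigned <- which(lin != "" & !startsWith(lin, "unclassified"))
    if (length(assigned) == length(upto)) {
      labels[i] <- lin[length(lin)]
    } else if (length(assigned) == 0L) {
      labels[i] <- "unclassified"
    } else {
      labels[i] <- paste0("unclassified_", lin[max(assigned)])
    }
  }
  agg <- rowsum(table$counts, group = labels, reorder = FALSE)
  out <- table
  out$counts <- agg
  out
}
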