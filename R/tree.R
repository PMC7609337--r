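#' Read and validate a rooted phylogenetic tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' diversity computations rely on: rooted topology, unique leaf labels, and
#' finite nonnegative branch lengths.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  tree
}

#' Simulate a random rooted OTU tree with named clades
#'
#' Generates a random bifurcating rooted topology with exponential branch
#' lengths and partitions the leaves into five monophyletic clades, named
#' after bacterial orders typical of vaginal and early-infant communities.
#' The clades give the simulator phylogenetically clustered structure:
#' transfer-prone OTUs are whole clades, as observed for Clostridiales,
#' Lactobacillales and Enterobacteriales in mother-infant cohorts.
#'
#' @param n_otus number of leaves (>= 10).
#' @param seed integer seed.
#' @param br_rate rate of the exponential branch-length distribution
#'   (mean branch length `1/br_rate`).
#' @return list with `tree` (a `phylo` with tips `OTU_0001`...) and `clade`
#'   (named character vector, clade label per OTU).
#' @export
simulate_tree <- function(n_otus, seed, br_rate = 10) {
  stopifnot(n_otus >= 10)
  set.seed(seed)
  tree <- ape::rtree(n_otus, rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = br_rate))
  tree$tip.label <- sprintf("OTU_%04d", seq_len(n_otus))
  clade_nodes <- partition_clades(tree, k = 5L)
  labels <- c("Lactobacillales", "Clostridiales", "Enterobacteriales",
              "Bacteroidales", "Pseudomonadales")
  # largest clade becomes the Lactobacillus-like clade
  sizes <- vapply(clade_nodes, length, 1L)
  ord <- order(sizes, decreasing = TRUE)
  clade <- character(n_otus)
  names(clade) <- tree$tip.label
  for (i in seq_along(ord)) {
    clade[clade_nodes[[ord[i]]]] <- labels[i]
  }
  list(tree = tree, clade = clade)
}

# Split a rooted bifurcating tree into k monophyletic leaf groups by
# repeatedly splitting the largest current clade at its root node.
partition_clades <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    out <- character(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[[1L]]; stack <- stack[-1L]
      ch <- kids(nd)
      out <- c(out, tree$tip.label[ch[ch <= n_tip]])
      stack <- c(stack, ch[ch > n_tip])
    }
    out
  }
  groups <- as.list(kids(root))
  while (length(groups) < k) {
    sizes <- vapply(groups, function(nd) {
      if (nd <= n_tip) 1L else length(tips_below(nd))
    }, 1L)
    splittable <- which(vapply(groups, function(nd) nd > n_tip, TRUE))
    if (!length(splittable)) stop("tree too small to form ", k, " clades")
    g <- splittable[which.max(sizes[splittable])]
    groups <- c(groups[-g], as.list(kids(groups[[g]])))
  }
  lapply(groups, function(nd) if (nd <= n_tip) tree$tip.label[nd] else tips_below(nd))
}

# Edge x leaf incidence: desc[e, i] is TRUE when leaf i lies below edge e.
# Shared by Faith's PD and the UniFrac family; computed once per tree and
# cached on the tree object by callers that loop over samples.
edge_leaf_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  desc <- matrix(FALSE, n_edge, n_tip,
                 dimnames = list(NULL, tree$tip.label))
  # postorder: children edges processed before their parent edge
  ord <- ape::reorder.phylo(tree, "postorder")
  # map node -> edge index in original ordering
  edge_idx <- match(ord$edge[, 2], tree$edge[, 2])
  for (j in seq_len(n_edge)) {
    e <- edge_idx[j]
    child <- tree$edge[e, 2]
    if (child <= n_tip) {
      desc[e, child] <- TRUE
    } else {
      below <- tree$edge[, 1] == child
      desc[e, ] <- colSums(desc[below, , drop = FALSE]) > 0
    }
  }
  desc
}
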