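#' Build the symmetric simulation phylogeny
#'
#' Constructs a fully balanced, ultrametric binary tree rooted at its
#' midpoint, with every edge set to the same divergence (expected number of
#' substitutions per codon site per branch). Tip labels `t1..tn` follow the
#' tree traversal order, which also fixes the row order of simulated
#' alignments.
#'
#' @param n_leaves number of leaves; must be a power of two in {2, 4, 8, 16}.
#' @param divergence positive branch length shared by every edge.
#' @return an [ape::phylo] tree with `2 * n_leaves - 1` nodes.
#' @export
#' @examples
#' tr <- build_symmetric_tree(8, 0.2)
#' sum(tr$edge.length)  # 14 edges x 0.2
build_symmetric_tree <- function(n_leaves = 8, divergence = 0.2) {
  if (length(n_leaves) != 1 || !(n_leaves %in% c(2, 4, 8, 16)))
    stop("n_leaves must be a power of two in {2, 4, 8, 16}", call. = FALSE)
  if (length(divergence) != 1 || !is.finite(divergence) || divergence <= 0)
    stop("divergence must be a positive number", call. = FALSE)
  tr <- ape::stree(n_leaves, type = "balanced")
  tr$edge.length <- rep(divergence, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

# children of every node, indexed by node number
.tree_children <- function(tree) {
  n_nodes <- max(tree$edge)
  kids <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

.tree_root <- function(tree) length(tree$tip.label) + 1L
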