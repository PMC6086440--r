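# The path distance between tree topologies and the machinery used to
# compute it cheaply over a whole trace (distances are needed once per
# distinct topology only).

# Vector of pairwise-leaf path lengths (edge counts) for one tree, taxa
# ordered alphabetically. Branch lengths are ignored: every edge counts
# 1. With unrooted = TRUE the root's degree-2 node is suppressed first.
pathCountVector <- function(tree, unrooted = FALSE) {
  if (unrooted && length(tree$tip.label) > 2)
    tree <- ape::unroot(tree)
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  ntip <- length(t1$tip.label)
  d <- ape::dist.nodes(t1)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  o <- order(t1$tip.label)
  d <- d[o, o, drop = FALSE]
  d[lower.tri(d)]
}

#' Path distance between two tree topologies
#'
#' For every unordered taxon pair (i, j), let \eqn{p_{ij}(T)} be the
#' number of edges on the path from i to j in T. The path distance is
#' the Euclidean distance between the two path-count vectors:
#' \eqn{\sqrt{\sum_{i<j} (p_{ij}(T_1) - p_{ij}(T_2))^2}}. Branch lengths
#' are ignored, making the metric invariant to clock scaling. By default
#' trees are treated as rooted, so the root's degree-2 node contributes
#' edges; \code{unrooted = TRUE} suppresses it.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param unrooted suppress the root node before counting (default
#'   FALSE, matching rooted clock trees).
#' @return non-negative real; 0 iff the topologies are identical.
#' @examples
#' pathDistance(parseNewick("((A,B),(C,D));"),
#'              parseNewick("((A,C),(B,D));"))  # 4
#' @export
pathDistance <- function(t1, t2, unrooted = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    diffs <- c(setdiff(t1$tip.label, t2$tip.label),
               setdiff(t2$tip.label, t1$tip.label))
    stopInput("leaf sets differ; symmetric difference: %s",
              paste(sort(diffs), collapse = ", "))
  }
  v1 <- pathCountVector(t1, unrooted)
  v2 <- pathCountVector(t2, unrooted)
  sqrt(sum((v1 - v2)^2))
}

# Path-count vectors for each distinct topology of a trace: a matrix
# [pair x topology]. Shared with both topological ESS estimators.
.topoPathMatrix <- function(topoIndex, unrooted = FALSE) {
  vapply(topoIndex$trees, pathCountVector, unrooted = unrooted,
         FUN.VALUE = pathCountVector(topoIndex$trees[[1]], unrooted))
}

# Distance between two distinct-topology columns, vectorised over pairs
# of column indices.
.topoDistance <- function(pathMat, i, j) {
  if (length(i) == 0) return(numeric())
  d2 <- colSums((pathMat[, i, drop = FALSE] -
                   pathMat[, j, drop = FALSE])^2)
  sqrt(d2)
}
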