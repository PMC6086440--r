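#' Node ages of an ultrametric tree
#'
#' Ages are measured backwards from the leaves: leaves have age 0 and
#' the age of an internal node is the tree height minus its depth, in
#' the units of the branch lengths (substitutions/site or Myr depending
#' on provenance). The tree must be ultrametric within a tolerance: all
#' root-to-leaf path lengths equal up to \code{tolerance}.
#'
#' @param tree a rooted \code{phylo} with complete branch lengths.
#' @param tolerance maximum allowed spread of root-to-leaf path lengths.
#'   The default is \code{1e-6 * height} (relative), which covers
#'   floating-point drift in exported trees.
#' @return named numeric vector of ages indexed by node id
#'   (tips first, then internal nodes; names are tip labels for tips).
#' @examples
#' nodeAges(parseNewick("((A:1,B:1):1,C:2);"))
#' @export
nodeAges <- function(tree, tolerance = NULL) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopInput("tree has missing branch lengths; ages are undefined")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- numeric(nn)
  # preorder accumulation of depths
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + ord$edge.length[i]
  }
  height <- max(depth[seq_len(ntip)])
  spread <- height - min(depth[seq_len(ntip)])
  if (is.null(tolerance)) tolerance <- 1e-6 * max(height, 1e-300)
  if (spread > tolerance)
    stopInput(paste0("tree is not ultrametric: root-to-leaf spread %g ",
                     "exceeds tolerance %g"), spread, tolerance)
  ages <- height - depth
  ages[seq_len(ntip)] <- 0
  names(ages) <- c(tree$tip.label, rep("", tree$Nnode))
  ages
}
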