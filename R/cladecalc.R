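# Clade extraction, posterior clade probabilities and monophyly tests
# reported as posterior odds, with 1/ESS_topology upper bounds when a
# hypothesised clade never occurs in the sample.

#' Extract the clades of a rooted tree
#'
#' One clade per internal node: the set of descendant leaf labels.
#' The root clade (full taxon set) is included; single-leaf sets are
#' not.
#'
#' @param tree a rooted \code{phylo}.
#' @return list of character vectors (sorted leaf labels), one per
#'   internal node, in node-id order.
#' @examples
#' extractClades(parseNewick("((A,B),C);"))
#' @export
extractClades <- function(tree) {
  sets <- descendantLeafSets(tree)
  ntip <- length(tree$tip.label)
  sets[(ntip + 1L):(ntip + tree$Nnode)]
}

#' Test whether a taxon set is monophyletic in a tree
#'
#' TRUE iff some node's descendant leaf set equals \code{taxa} exactly.
#' Evaluated on the rooted tree: the clades of a clock tree are rooted
#' clades, not unrooted bipartitions.
#'
#' @param tree a rooted \code{phylo}.
#' @param taxa character vector of leaf labels, a subset of the tree's
#'   leaves.
#' @return logical.
#' @examples
#' isMonophyletic(parseNewick("((A,B),C);"), c("A", "B"))   # TRUE
#' isMonophyletic(parseNewick("((A,B),C);"), c("A", "C"))   # FALSE
#' @export
isMonophyletic <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stopInput("taxa not present in the tree: %s",
              paste(unknown, collapse = ", "))
  key <- cladeKey(taxa)
  any(vapply(extractClades(tree), function(s) cladeKey(s) == key, TRUE))
}

# Clade membership per distinct topology of a trace; returns a logical
# matrix [distinct topology x clade]. `clades` is a list of taxon sets.
.cladeMembership <- function(topoIndex, clades) {
  keys <- vapply(clades, cladeKey, "")
  vapply(seq_along(keys), function(j) {
    vapply(topoIndex$trees, function(tr) {
      any(vapply(extractClades(tr), cladeKey, "") == keys[j])
    }, TRUE)
  }, logical(length(topoIndex$trees)))
}

#' Posterior probability of a clade
#'
#' Estimated as the frequency of trees in the posterior sample that
#' contain the clade (some node's descendant leaf set equals the taxon
#' set exactly).
#'
#' @param trace a \linkS4class{TreeTrace}.
#' @param taxa a single taxon set (character vector) or a list of taxon
#'   sets; a list is evaluated in one pass over the trace.
#' @return numeric vector of frequencies in \[0, 1\], one per clade.
#' @examples
#' tr <- treeTrace(lapply(c("((A,B),C);", "((A,C),B);"), parseNewick))
#' cladePosterior(tr, c("A", "B"))  # 0.5
#' @export
cladePosterior <- function(trace, taxa) {
  if (!is.list(taxa)) taxa <- list(taxa)
  unknown <- setdiff(unique(unlist(taxa)), trace@taxa)
  if (length(unknown))
    stopInput("taxa not present in the trace: %s",
              paste(unknown, collapse = ", "))
  idx <- traceTopologyIndex(trace)
  member <- .cladeMembership(idx, taxa)
  member <- matrix(member, nrow = length(idx$trees))
  counts <- tabulate(idx$ids, nbins = length(idx$trees))
  as.numeric(crossprod(member, counts) / length(trace))
}

#' Posterior odds of a hypothesis probability
#'
#' The posterior odds \eqn{P(H|D) / (1 - P(H|D))}: how many times more
#' likely the hypothesis is than its complement under the posterior.
#' Only defined for exact probabilities strictly inside (0, 1); clade
#' frequencies of 0 or 1 must go through the bound path of
#' \code{\link{monophylyTest}}.
#'
#' @param p posterior probability in (0, 1).
#' @return non-negative real.
#' @examples
#' round(posteriorOdds(0.096), 3)  # 0.106
#' @export
posteriorOdds <- function(p) {
  if (any(p <= 0 | p >= 1))
    stopInput(paste0("posterior odds are undefined at p = 0 or 1; ",
                     "use monophylyTest for the 1/ESS bound path"))
  p / (1 - p)
}

#' Monophyly test from a posterior tree sample
#'
#' Tests whether the hypothesised taxon set forms a clade, reporting the
#' posterior probability and posterior odds. When the clade frequency is
#' strictly between 0 and 1 both are exact. When the clade occurs in no
#' sampled tree, only an upper bound is available:
#' \eqn{P(H|D) < 1/ESS_{topology}}, reported for both topological ESS
#' bases — "P" (pseudo-ESS) and "A" (approximate ESS) — with the odds
#' bound \eqn{b/(1-b)}. A clade present in every sampled tree (e.g. the
#' root clade) yields the symmetric lower bound
#' \eqn{P(H|D) > 1 - 1/ESS_{topology}}.
#'
#' @param trace a \linkS4class{TreeTrace}.
#' @param taxa hypothesised taxon set (character vector).
#' @param ess an \linkS4class{ESSReport} computed on the same trace
#'   (see \code{\link{essReport}}); required fields are the pseudo and
#'   approximate topological ESS.
#' @param name hypothesis name for reporting (e.g. "H1").
#' @return a \linkS4class{MonophylyResult}.
#' @examples
#' trees <- c(rep("((A,B),C);", 3), "((A,C),B);")
#' tr <- treeTrace(lapply(trees, parseNewick))
#' ess <- new("ESSReport", n = 4L, pseudo = 4, approx = 4,
#'            pseudoReplicates = 4)
#' monophylyTest(tr, c("A", "B"), ess, name = "H1")
#' @export
monophylyTest <- function(trace, taxa, ess, name = "H") {
  if (!is(ess, "ESSReport")) stopInput("ess must be an ESSReport")
  essP <- ess@pseudo
  essA <- ess@approx
  if ((is.na(essP) || essP < 1) && (is.na(essA) || essA < 1))
    stopInput("topological ESS missing or < 1; cannot bound P(H|D)")
  n <- length(trace)
  p <- cladePosterior(trace, taxa)
  count <- as.integer(round(p * n))
  if (p > 0 && p < 1) {
    res <- new("MonophylyResult", hypothesis = name, taxa = sort(taxa),
               probability = p, odds = p / (1 - p), bound = "none",
               n = as.integer(n), count = count)
    return(res)
  }
  # bound path: P < 1/ESS (frequency 0) or P > 1 - 1/ESS (frequency 1),
  # per ESS basis; the bound is exactly 1/ESS, rounding happens only in
  # the report layer.
  bounds <- c(P = 1 / essP, A = 1 / essA)
  if (p == 0) {
    new("MonophylyResult", hypothesis = name, taxa = sort(taxa),
        probability = bounds, odds = bounds / (1 - bounds),
        bound = "upper", n = as.integer(n), count = count)
  } else {
    pb <- 1 - bounds
    new("MonophylyResult", hypothesis = name, taxa = sort(taxa),
        probability = pb, odds = pb / (1 - pb), bound = "lower",
        n = as.integer(n), count = count)
  }
}
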