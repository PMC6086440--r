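# Oracle generator: an autocorrelated Markov chain over the finite set
# of rooted topologies with a known stationary law. The "sticky"
# regeneration kernel (stay with probability alpha, else redraw from pi)
# is used precisely because its stationary distribution and
# autocorrelation time (1+alpha)/(1-alpha) are exact in closed form.

#' Enumerate all rooted binary labelled topologies
#'
#' Builds every distinct rooted binary topology on the given taxa by
#' sequential insertion, in a deterministic order. There are
#' \eqn{(2n-3)!!} such topologies; the taxon count is capped at 6 (105
#' topologies) as a combinatorial guard.
#'
#' @param taxa character vector of 2..6 taxon labels.
#' @return list of \code{phylo} trees (no branch lengths).
#' @examples
#' length(enumerateRootedTopologies(c("A", "B", "C", "D")))  # 15
#' @export
enumerateRootedTopologies <- function(taxa) {
  n <- length(taxa)
  if (n < 2) stopInput("need at least 2 taxa")
  if (n > 6) stopInput("enumeration capped at 6 taxa (%d requested)", n)
  # nested-list representation: leaf = label, internal = list(a, b)
  trees <- list(list(taxa[1], taxa[2]))
  if (n > 2) {
    for (k in 3:n) {
      x <- taxa[k]
      nxt <- list()
      for (tr in trees) {
        # attach above every node (preorder), then above the root
        positions <- .insertEverywhere(tr, x)
        nxt <- c(nxt, positions, list(list(tr, x)))
      }
      trees <- nxt
    }
  }
  lapply(trees, function(tr) parseNewick(paste0(.nestedToNewick(tr), ";")))
}

# All trees obtained by attaching x above a node *within* tr (root
# attachment is handled by the caller). Returns a list of new trees.
.insertEverywhere <- function(tr, x) {
  if (!is.list(tr)) return(list())   # leaf has no internal positions
  out <- list()
  for (side in 1:2) {
    child <- tr[[side]]
    # attach above this child
    mod <- tr
    mod[[side]] <- list(child, x)
    out <- c(out, list(mod))
    # or deeper inside it
    for (sub in .insertEverywhere(child, x)) {
      mod <- tr
      mod[[side]] <- sub
      out <- c(out, list(mod))
    }
  }
  out
}

.nestedToNewick <- function(tr) {
  if (!is.list(tr)) return(tr)
  paste0("(", .nestedToNewick(tr[[1]]), ",", .nestedToNewick(tr[[2]]),
         ")")
}

#' Sample a sticky chain over rooted topologies
#'
#' At each step the chain stays at the current topology with probability
#' \code{alpha} and otherwise draws afresh from the stationary
#' distribution \code{pi}. The stationary law is exactly \code{pi}, the
#' lag-k autocorrelation of any topology indicator is \eqn{\alpha^k},
#' and the autocorrelation time is \eqn{(1+\alpha)/(1-\alpha)} — all
#' recorded in the returned \linkS4class{SimTruth}.
#'
#' @param config a \linkS4class{StickyChainConfig}. An empty \code{pi}
#'   slot draws the stationary distribution from a symmetric
#'   Dirichlet(1) under the seed.
#' @return list with \code{trace} (a \linkS4class{TreeTrace}) and
#'   \code{truth} (a \linkS4class{SimTruth}).
#' @examples
#' cfg <- stickyChainConfig(LETTERS[1:4], alpha = 0.5, n = 50, seed = 7)
#' out <- sampleStickyChain(cfg)
#' length(out$trace)
#' @export
sampleStickyChain <- function(config) {
  validObject(config)
  topos <- enumerateRootedTopologies(config@taxa)
  k <- length(topos)
  pi <- config@pi
  ids <- withSeed(config@seed, {
    if (!length(pi)) {
      g <- rgamma(k, shape = 1)
      pi <- g / sum(g)
    }
    if (length(pi) != k)
      stopInput("pi has %d entries but there are %d topologies",
                length(pi), k)
    n <- config@n
    fresh <- sample.int(k, n, replace = TRUE, prob = pi)
    stay <- runif(n) < config@alpha
    out <- integer(n)
    out[1] <- fresh[1]
    for (t in seq_len(n)[-1])
      out[t] <- if (stay[t]) out[t - 1L] else fresh[t]
    out
  })
  trace <- new("TreeTrace", trees = topos[ids],
               sampleIndex = seq_along(ids),
               taxa = sort(config@taxa), burnin = 0,
               source = sprintf("sticky chain (alpha=%g, seed=%d)",
                                config@alpha, config@seed))
  truth <- new("SimTruth", pi = pi, topologyIds = ids,
               act = (1 + config@alpha) / (1 - config@alpha),
               taxa = config@taxa)
  attr(truth, "topologies") <- topos
  list(trace = trace, truth = truth)
}

#' Exact clade probability under a sticky chain's stationary law
#'
#' Computed by enumeration: the sum of \code{pi} over all topologies in
#' which the taxon set is monophyletic. This is the oracle against which
#' \code{\link{cladePosterior}} estimates are checked.
#'
#' @param truth a \linkS4class{SimTruth} from
#'   \code{\link{sampleStickyChain}}.
#' @param taxa a taxon set or list of taxon sets.
#' @return numeric vector of exact probabilities.
#' @export
trueCladeProbability <- function(truth, taxa) {
  topos <- attr(truth, "topologies")
  if (is.null(topos)) topos <- enumerateRootedTopologies(truth@taxa)
  if (!is.list(taxa)) taxa <- list(taxa)
  vapply(taxa, function(tx) {
    member <- vapply(topos, isMonophyletic, TRUE, taxa = tx)
    sum(truth@pi[member])
  }, 0)
}

#' Write the ground truth of a synthetic run as a JSON sidecar
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSimTruth <- function(truth, path) {
  x <- list(act = truth@act, taxa = truth@taxa)
  if (length(truth@pi)) x$pi <- truth@pi
  if (length(truth@topologyIds)) x$topologyIds <- truth@topologyIds
  if (!is.null(truth@trueTree))
    x$trueTree <- writeNewick(truth@trueTree)
  if (length(truth@branchRates)) x$branchRates <- truth@branchRates
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}
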