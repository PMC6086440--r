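# Generative model: ultrametric birth-death trees, uncorrelated
# lognormal branch rates, and GTR+G+I sequence evolution. Used both as
# a prior-predictive generator and as the oracle for summarisation and
# end-to-end tests.

#' Mean-based discrete gamma rate categories
#'
#' Equal-probability discretisation of a Gamma(shape, rate = shape)
#' distribution (mean 1) into \code{k} categories, each represented by
#' its conditional mean — the convention of standard likelihood
#' software. Category means average to exactly 1 by construction.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return numeric vector of k rate multipliers, mean 1.
#' @examples
#' mean(discreteGammaRates(11.1, 6))  # 1
#' @export
discreteGammaRates <- function(shape, k) {
  if (shape <= 0 || k < 1) stopInput("invalid gamma discretisation")
  if (k == 1) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # E[X; X <= q] for X ~ Gamma(a, rate = a) equals pgamma(q, a+1, a)
  cum <- pgamma(q, shape = shape + 1, rate = shape)
  k * diff(cum)
}

#' Simulate an ultrametric birth-death tree with n extant tips
#'
#' Forward simulation from a crown pair of lineages, with speciation
#' rate \code{birthRate} and extinction rate \code{birthRate *
#' relativeDeathRate}. The process is stopped the first time the number
#' of extant lineages reaches \code{nTaxa}, extended by a uniform
#' fraction of the next inter-event waiting time (so terminal branches
#' are positive), and conditioned on reaching \code{nTaxa} by rejection.
#' Extinct lineages are pruned; ages are in Myr.
#'
#' @param config a \linkS4class{SeqSimConfig} (uses nTaxa, birthRate,
#'   relativeDeathRate, seed).
#' @param maxAttempts rejection budget (default 1e5).
#' @return an ultrametric rooted \code{phylo} with \code{nTaxa} tips
#'   labelled t1..tn.
#' @examples
#' tr <- simulateBDTree(seqSimConfig(nTaxa = 5, birthRate = 1, seed = 3))
#' max(nodeAges(tr)) > 0
#' @export
simulateBDTree <- function(config, maxAttempts = 1e5) {
  validObject(config)
  n <- config@nTaxa
  b <- config@birthRate
  d <- b * config@relativeDeathRate
  withSeed(config@seed, {
    for (attempt in seq_len(maxAttempts)) {
      tr <- .bdForwardOnce(n, b, d)
      if (!is.null(tr)) return(tr)
    }
    stopInput(paste0("birth-death rejection budget (%d) exhausted; ",
                     "raise birthRate or lower relativeDeathRate"),
              maxAttempts)
  })
}

# One forward pass; NULL when the process dies out before reaching n
# extant lineages. Event budget guards pathological parameter choices.
.bdForwardOnce <- function(n, b, d, maxEvents = 10000L) {
  # lineage bookkeeping: parent node, birth time, end time, status
  parent <- c(NA_integer_, 1L, 1L)
  start <- c(0, 0, 0)
  end <- c(0, NA_real_, NA_real_)     # node 1 is the crown split
  alive <- c(FALSE, TRUE, TRUE)
  isTip <- c(FALSE, TRUE, TRUE)
  time <- 0
  if (n == 2) {
    tail <- rexp(1, (b + d) * 2) * runif(1)
    end[alive] <- tail
    return(.bdBuildPhylo(parent, start, end, isTip, alive, tail))
  }
  for (ev in seq_len(maxEvents)) {
    k <- sum(alive)
    if (k == 0) return(NULL)
    wait <- rexp(1, (b + d) * k)
    time <- time + wait
    if (k == n) {
      # first passage to n: freeze a uniform fraction before the next
      # event so all terminal branches are positive
      tfinal <- time - wait + wait * runif(1)
      end[alive] <- tfinal
      return(.bdBuildPhylo(parent, start, end, isTip, alive, tfinal))
    }
    who <- which(alive)[sample.int(k, 1)]
    if (runif(1) < b / (b + d)) {
      # speciation: lineage becomes an internal node with two children
      end[who] <- time
      alive[who] <- FALSE
      isTip[who] <- FALSE
      parent <- c(parent, who, who)
      start <- c(start, time, time)
      end <- c(end, NA_real_, NA_real_)
      alive <- c(alive, TRUE, TRUE)
      isTip <- c(isTip, TRUE, TRUE)
    } else {
      end[who] <- time
      alive[who] <- FALSE   # extinct tip, stays isTip
    }
  }
  NULL
}

# Convert lineage records to a pruned, ultrametric phylo.
.bdBuildPhylo <- function(parent, start, end, isTip, alive, tfinal) {
  tips <- which(isTip)
  ints <- which(!isTip)
  ntip <- length(tips)
  id <- integer(length(parent))
  id[tips] <- seq_len(ntip)
  id[ints] <- ntip + seq_along(ints)
  edge <- cbind(id[parent[-1]], id[-1])
  elen <- (end - start)[-1]
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0("x", seq_len(ntip)), Nnode = length(ints))
  class(tr) <- "phylo"
  extinct <- tr$tip.label[!alive[tips]]
  if (length(extinct))
    tr <- ape::drop.tip(tr, extinct, collapse.singles = TRUE)
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  tr
}

#' Draw uncorrelated lognormal branch rates
#'
#' One i.i.d. lognormal rate per branch, parameterised so the
#' real-scale mean equals \code{ucldMean} and the log-scale standard
#' deviation equals \code{ucldStdev} (log-scale mean
#' \eqn{\ln(ucldMean) - ucldStdev^2/2}). \code{ucldStdev = 0} is a
#' strict clock.
#'
#' @param tree a \code{phylo}; one rate per row of \code{tree$edge}.
#' @param ucldMean real-scale mean rate (substitutions/site/Myr).
#' @param ucldStdev log-scale standard deviation (>= 0).
#' @param seed RNG seed.
#' @return numeric vector of per-branch rates, aligned with
#'   \code{tree$edge}.
#' @export
assignRelaxedRates <- function(tree, ucldMean, ucldStdev, seed = 1L) {
  if (ucldMean <= 0) stopInput("ucldMean must be > 0")
  if (ucldStdev < 0) stopInput("ucldStdev must be >= 0")
  ne <- nrow(tree$edge)
  if (ucldStdev == 0) return(rep(ucldMean, ne))
  withSeed(seed, rlnorm(ne, meanlog = log(ucldMean) - ucldStdev^2 / 2,
                        sdlog = ucldStdev))
}

# GTR rate matrix (order A, C, G, T) normalised so the expected
# substitution rate at equilibrium is 1: branch lengths are then
# expected substitutions per site.
gtrRateMatrix <- function(rates, freqs) {
  if (any(rates <= 0)) stopInput("exchangeabilities must be positive")
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  Q[1, 2] <- rates[1]; Q[1, 3] <- rates[2]; Q[1, 4] <- rates[3]
  Q[2, 3] <- rates[4]; Q[2, 4] <- rates[5]; Q[3, 4] <- rates[6]
  Q <- Q + t(Q)
  Q <- Q * rep(freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Eigen machinery for P(t) = exp(Qt) of a reversible Q: symmetrise with
# the stationary frequencies, decompose once, exponentiate per t.
.gtrEigen <- function(Q, freqs) {
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = diag(1 / s) %*% e$vectors, Uinv = t(e$vectors) %*% diag(s),
       lambda = e$values)
}

.gtrTransition <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an alignment under GTR+G+I with per-branch rates
#'
#' Each site is invariant with probability \code{pInv}; otherwise it
#' receives a rate multiplier from the mean-based discrete gamma
#' categories. Characters evolve from a root draw out of the
#' equilibrium frequencies, with expected substitutions on a branch
#' equal to branch duration x branch rate x site multiplier (the GTR
#' matrix is normalised to one expected substitution per unit).
#'
#' @param tree a rooted \code{phylo} with branch lengths (durations,
#'   Myr).
#' @param rates per-branch clock rates aligned with \code{tree$edge}
#'   (see \code{\link{assignRelaxedRates}}), or a single rate.
#' @param config a \linkS4class{SeqSimConfig} (GTR, gamma, pInv, length,
#'   seed).
#' @return a \code{Biostrings::DNAStringSet} of tip sequences.
#' @examples
#' cfg <- seqSimConfig(nTaxa = 2, length = 100, pInv = 1)
#' tr <- parseNewick("(A:1,B:1);")
#' simulateAlignment(tr, 0.01, cfg)   # all-constant columns
#' @export
simulateAlignment <- function(tree, rates, config) {
  validObject(config)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopInput("tree needs complete branch lengths")
  ne <- nrow(tree$edge)
  if (length(rates) == 1) rates <- rep(rates, ne)
  if (length(rates) != ne)
    stopInput("need one clock rate per branch (%d != %d)",
              length(rates), ne)
  L <- config@length
  Q <- gtrRateMatrix(config@gtrRates, config@baseFreq)
  eig <- .gtrEigen(Q, config@baseFreq)
  gam <- discreteGammaRates(config@gammaShape, config@gammaCategories)

  withSeed(deriveSeed(config@seed, "alignment"), {
    inv <- runif(L) < config@pInv
    mult <- numeric(L)
    mult[!inv] <- gam[sample.int(length(gam), sum(!inv), replace = TRUE)]
    states <- matrix(0L, nrow = length(tree$tip.label) + tree$Nnode,
                     ncol = L)
    root <- rootNode(tree)
    states[root, ] <- sample.int(4, L, replace = TRUE,
                                 prob = config@baseFreq)
    ord <- ape::reorder.phylo(tree, "cladewise")
    eo <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
    for (i in seq_len(ne)) {
      p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
      dur <- ord$edge.length[i] * rates[eo[i]]
      child <- states[p, ]
      for (g in unique(mult[mult > 0])) {
        sites <- which(mult == g)
        if (!length(sites)) next
        P <- .gtrTransition(eig, dur * g)
        ps <- states[p, sites]
        for (s in 1:4) {
          here <- sites[ps == s]
          if (length(here))
            child[here] <- sample.int(4, length(here), replace = TRUE,
                                      prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    ntip <- length(tree$tip.label)
    chars <- c("A", "C", "G", "T")
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                  function(r) paste(chars[r], collapse = ""))
    Biostrings::DNAStringSet(setNames(seqs, tree$tip.label))
  })
}

#' Draw a model configuration from the generative priors
#'
#' Prior-predictive generator: speciation rate from Lognormal(1, 1.25)
#' (log-scale parameters), relative extinction from Beta(1, 2),
#' relative exchangeabilities from Gamma(shape 1, scale 1), base
#' frequencies from a symmetric Dirichlet(1), \code{ucldStdev} from
#' Gamma(shape 0.5396, scale 0.3819) and the invariant-site proportion
#' from Uniform(0, 1). The clock mean is fixed by mode: 0.0115
#' substitutions/site/Myr (mitochondrial, the standard arthropod rate)
#' or 0.004 (nuclear).
#'
#' @param seed RNG seed.
#' @param mode "mitochondrial" (default) or "nuclear".
#' @param nTaxa,length tree and alignment sizes for the resulting
#'   config.
#' @return a \linkS4class{SeqSimConfig}.
#' @examples
#' sampleModelPriors(1)@ucldMean  # 0.0115
#' @export
sampleModelPriors <- function(seed = 1L,
                              mode = c("mitochondrial", "nuclear"),
                              nTaxa = 8L, length = 658L) {
  mode <- match.arg(mode)
  withSeed(seed, {
    seqSimConfig(
      nTaxa = nTaxa,
      birthRate = rlnorm(1, meanlog = 1, sdlog = 1.25),
      relativeDeathRate = rbeta(1, 1, 2),
      ucldMean = if (mode == "mitochondrial") 0.0115 else 0.004,
      ucldStdev = rgamma(1, shape = 0.5396, scale = 0.3819),
      gtrRates = rgamma(6, shape = 1, scale = 1),
      baseFreq = local({ g <- rgamma(4, 1); g / sum(g) }),
      gammaShape = 11.1, gammaCategories = 6L,
      pInv = runif(1), length = length, seed = seed)
  })
}
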