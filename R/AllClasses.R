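#' @import methods
#' @importFrom stats acf median qgamma pgamma rbeta rgamma rlnorm runif rbinom rexp rnorm setNames quantile var
#' @importFrom utils head tail
NULL

setOldClass("phylo")

#' Pipeline configuration
#'
#' Holds the handful of knobs shared across the pipeline: the burn-in
#' fraction applied when reading tree traces, the HPD mass used for
#' credible intervals, the scalar-ESS convergence gate, the RNG seed and
#' the rounding rules used by the report layer.
#'
#' @slot burnin burn-in fraction in \[0, 1); applied to retained
#'   (post-thinning) samples, not generations.
#' @slot hpdLevel HPD mass in (0, 1).
#' @slot essThreshold convergence gate: every ESS must exceed this.
#' @slot seed integer RNG seed used for all stochastic steps.
#' @slot oddsDigits decimal places for exact posterior odds in reports.
#' @slot boundSigFigs significant figures for ESS-based bounds in reports.
#'
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    burnin = "numeric",
    hpdLevel = "numeric",
    essThreshold = "numeric",
    seed = "integer",
    oddsDigits = "integer",
    boundSigFigs = "integer"
  ),
  prototype(
    burnin = 0.10, hpdLevel = 0.95, essThreshold = 200,
    seed = 1L, oddsDigits = 3L, boundSigFigs = 2L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@burnin < 0 || object@burnin >= 1)
    msg <- c(msg, "burnin must lie in [0, 1)")
  if (object@hpdLevel <= 0 || object@hpdLevel >= 1)
    msg <- c(msg, "hpdLevel must lie in (0, 1)")
  if (object@essThreshold <= 0)
    msg <- c(msg, "essThreshold must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param burnin burn-in fraction in \[0,1) (default 0.10).
#' @param hpdLevel HPD mass (default 0.95).
#' @param essThreshold scalar ESS gate (default 200).
#' @param seed integer RNG seed.
#' @param oddsDigits decimals for exact odds (default 3).
#' @param boundSigFigs significant figures for bounds (default 2).
#' @return a \linkS4class{PipelineConfig}.
#' @examples
#' pipelineConfig(seed = 42L)
#' @export
pipelineConfig <- function(burnin = 0.10, hpdLevel = 0.95,
                           essThreshold = 200, seed = 1L,
                           oddsDigits = 3L, boundSigFigs = 2L) {
  new("PipelineConfig", burnin = burnin, hpdLevel = hpdLevel,
      essThreshold = essThreshold, seed = as.integer(seed),
      oddsDigits = as.integer(oddsDigits),
      boundSigFigs = as.integer(boundSigFigs))
}

#' Ordered posterior sample of rooted trees
#'
#' A \code{TreeTrace} is an ordered post-burn-in sample of rooted trees
#' sharing one taxon set, as produced by a Bayesian tree sampler after
#' thinning. Trees are \code{ape} \code{phylo} objects.
#'
#' @slot trees list of \code{phylo} trees with identical leaf label sets.
#' @slot sampleIndex integer sample index (generation) per tree, strictly
#'   increasing.
#' @slot taxa the shared taxon set (sorted).
#' @slot burnin burn-in fraction already applied to this trace.
#' @slot source free-text provenance (file name, simulator call).
#'
#' @exportClass TreeTrace
setClass("TreeTrace",
  representation(
    trees = "list",
    sampleIndex = "integer",
    taxa = "character",
    burnin = "numeric",
    source = "character"
  )
)

setValidity("TreeTrace", function(object) {
  msg <- character()
  n <- length(object@trees)
  if (n < 1) msg <- c(msg, "trace must contain at least one tree")
  if (length(object@sampleIndex) != n)
    msg <- c(msg, "sampleIndex length must equal number of trees")
  if (n > 1 && any(diff(object@sampleIndex) <= 0))
    msg <- c(msg, "sample indices must be strictly increasing")
  if (object@burnin < 0 || object@burnin >= 1)
    msg <- c(msg, "burnin must lie in [0, 1)")
  if (n >= 1) {
    for (i in seq_len(n)) {
      tr <- object@trees[[i]]
      if (!inherits(tr, "phylo")) {
        msg <- c(msg, sprintf("element %d is not a phylo tree", i))
        break
      }
      if (!setequal(tr$tip.label, object@taxa)) {
        msg <- c(msg, sprintf(
          "tree %d has a different taxon set (%s)", i,
          paste(sort(tr$tip.label), collapse = ",")))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TreeTrace
#'
#' @param trees list of rooted \code{phylo} trees on a common taxon set.
#' @param sampleIndex optional integer sample indices (default 1..N).
#' @param burnin burn-in fraction already applied (metadata only).
#' @param source provenance string.
#' @return a \linkS4class{TreeTrace}.
#' @examples
#' t1 <- parseNewick("((A:1,B:1):1,C:2);")
#' t2 <- parseNewick("((A:1,C:1):1,B:2);")
#' treeTrace(list(t1, t2))
#' @export
treeTrace <- function(trees, sampleIndex = NULL, burnin = 0,
                      source = "in-memory") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(sampleIndex)) sampleIndex <- seq_along(trees)
  taxa <- if (length(trees)) sort(trees[[1]]$tip.label) else character()
  new("TreeTrace", trees = trees, sampleIndex = as.integer(sampleIndex),
      taxa = taxa, burnin = burnin, source = source)
}

#' @describeIn TreeTrace-class number of trees in the trace.
#' @param x a \code{TreeTrace}.
#' @export
setMethod("length", "TreeTrace", function(x) length(x@trees))

#' @describeIn TreeTrace-class subset the trace, keeping metadata aligned.
#' @param i indices of trees to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TreeTrace", function(x, i, j, ..., drop = TRUE) {
  idx <- x@sampleIndex[i]
  # permutation/duplication subsets lose the original indices
  if (length(idx) > 1 && any(diff(idx) <= 0)) idx <- seq_along(idx)
  new("TreeTrace", trees = x@trees[i], sampleIndex = idx,
      taxa = x@taxa, burnin = x@burnin, source = x@source)
})

setMethod("show", "TreeTrace", function(object) {
  cat(sprintf(
    "TreeTrace: %d trees, %d taxa (%s)\n  burn-in applied: %.0f%%  source: %s\n",
    length(object@trees), length(object@taxa),
    paste(head(object@taxa, 4), collapse = ", "),
    100 * object@burnin, object@source))
})

#' Trees in a trace
#' @param x a \code{TreeTrace}.
#' @return list of \code{phylo} objects.
#' @export
traceTrees <- function(x) x@trees

#' Taxon set of a trace
#' @param x a \code{TreeTrace}.
#' @return sorted character vector of leaf labels.
#' @export
traceTaxa <- function(x) x@taxa

#' Pool several traces (e.g. independent MCMC chains)
#'
#' Pooling is always explicit: independent chains are read as separate
#' traces and combined only through this function.
#'
#' @param ... \code{TreeTrace} objects on the same taxon set.
#' @return a pooled \code{TreeTrace}; sample indices are renumbered.
#' @export
poolTraces <- function(...) {
  traces <- list(...)
  if (length(traces) == 1 && is.list(traces[[1]]) &&
      !inherits(traces[[1]], "TreeTrace"))
    traces <- traces[[1]]
  stopifnot(length(traces) >= 1)
  taxa <- traces[[1]]@taxa
  for (tr in traces)
    if (!identical(tr@taxa, taxa))
      stop("cannot pool traces with different taxon sets")
  trees <- unlist(lapply(traces, function(tr) tr@trees), recursive = FALSE)
  treeTrace(trees, burnin = traces[[1]]@burnin,
            source = paste(vapply(traces, function(tr) tr@source, ""),
                           collapse = " + "))
}

#' Effective-sample-size report
#'
#' Collects the scalar ESS of named parameter traces together with the two
#' topological ESS estimates for a tree trace: the pseudo-ESS (median over
#' focal-tree replicates of the ESS of the path-distance series) and the
#' approximate ESS (from the autocorrelation of topological distances).
#'
#' @slot n trace length.
#' @slot scalar named numeric vector of scalar ESS values.
#' @slot pseudoReplicates per-focal-tree pseudo-ESS values.
#' @slot pseudo median of \code{pseudoReplicates} (ESS_topology, basis "P").
#' @slot approx approximate topological ESS (basis "A").
#' @slot threshold the gate threshold the report was built with.
#' @slot seed seed used for focal-tree and random-pair sampling.
#'
#' @exportClass ESSReport
setClass("ESSReport",
  representation(
    n = "integer",
    scalar = "numeric",
    pseudoReplicates = "numeric",
    pseudo = "numeric",
    approx = "numeric",
    threshold = "numeric",
    seed = "integer"
  ),
  prototype(n = 0L, scalar = numeric(), pseudoReplicates = numeric(),
            pseudo = NA_real_, approx = NA_real_, threshold = 200,
            seed = 1L)
)

setValidity("ESSReport", function(object) {
  msg <- character()
  ok <- function(v) all(is.na(v) | (v >= 1 & v <= object@n + 1e-8))
  if (!ok(object@scalar)) msg <- c(msg, "scalar ESS outside [1, N]")
  if (!ok(object@pseudo)) msg <- c(msg, "pseudo ESS outside [1, N]")
  if (!ok(object@approx)) msg <- c(msg, "approx ESS outside [1, N]")
  if (length(object@pseudoReplicates) && !is.na(object@pseudo) &&
      abs(object@pseudo - median(object@pseudoReplicates)) > 1e-8)
    msg <- c(msg, "pseudo must equal the median of pseudoReplicates")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ESSReport", function(object) {
  cat(sprintf("ESSReport (N = %d)\n", object@n))
  if (length(object@scalar))
    cat("  scalar ESS:",
        paste(sprintf("%s=%.1f", names(object@scalar), object@scalar),
              collapse = ", "), "\n")
  cat(sprintf("  topological pseudo-ESS (P): %.1f (%d replicates)\n",
              object@pseudo, length(object@pseudoReplicates)))
  cat(sprintf("  topological approx-ESS (A): %.1f\n", object@approx))
})

#' Result of a clade monophyly test
#'
#' When the clade's posterior frequency lies strictly between 0 and 1 the
#' posterior probability and odds are exact values. When the frequency is
#' 0 (the clade never occurs in the sample) only an upper bound
#' \eqn{P(H|D) < 1/ESS_{topology}} can be reported, one per ESS basis:
#' "P" (pseudo-ESS) and "A" (approximate ESS). Frequency 1 yields the
#' symmetric lower bound \eqn{P(H|D) > 1 - 1/ESS_{topology}}.
#'
#' @slot hypothesis hypothesis name.
#' @slot taxa the tested taxon set.
#' @slot probability exact value (length 1, basis "") or per-basis bounds
#'   (named "P", "A").
#' @slot odds exact posterior odds or per-basis bounds, same shape.
#' @slot bound "none", "upper" or "lower".
#' @slot n trace length the frequency was estimated from.
#' @slot count number of sampled trees containing the clade.
#'
#' @exportClass MonophylyResult
setClass("MonophylyResult",
  representation(
    hypothesis = "character",
    taxa = "character",
    probability = "numeric",
    odds = "numeric",
    bound = "character",
    n = "integer",
    count = "integer"
  )
)

setValidity("MonophylyResult", function(object) {
  msg <- character()
  if (!object@bound %in% c("none", "upper", "lower"))
    msg <- c(msg, "bound must be one of none/upper/lower")
  if (any(object@probability < 0 | object@probability > 1, na.rm = TRUE))
    msg <- c(msg, "probability outside [0, 1]")
  if (object@bound == "none") {
    p <- object@probability
    if (length(p) != 1 || p <= 0 || p >= 1)
      msg <- c(msg, "exact results require a single P in (0, 1)")
    else if (abs(object@odds - p / (1 - p)) > 1e-12 * max(1, object@odds))
      msg <- c(msg, "odds must equal P/(1-P) exactly")
  } else if (!all(c("P", "A") %in% names(object@probability))) {
    msg <- c(msg, "bounded results must carry both ESS bases (P and A)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MonophylyResult", function(object) {
  cat(sprintf("MonophylyResult: %s (%d taxa, N = %d)\n",
              object@hypothesis, length(object@taxa), object@n))
  cat(sprintf("  P(H|D): %s\n  odds:   %s\n",
              formatProbabilityCell(object),
              formatOddsCell(object)))
})

#' MCC tree with per-node age summaries
#'
#' The maximum-clade-credibility tree drawn from a posterior sample,
#' annotated (after \code{\link{annotateAges}}) with per-clade support,
#' posterior median ages and HPD intervals.
#'
#' @slot tree the MCC \code{phylo} tree (a sampled tree, never synthesised).
#' @slot summaries data.frame with one row per internal clade: clade key,
#'   support, count, median age, HPD bounds, HPD level, low-support flag.
#' @slot score the MCC log-score (sum of log clade frequencies).
#' @slot tie TRUE if another sampled topology achieved the same score.
#'
#' @exportClass AnnotatedTree
setClass("AnnotatedTree",
  representation(
    tree = "phylo",
    summaries = "data.frame",
    score = "numeric",
    tie = "logical"
  ),
  prototype(score = NA_real_, tie = FALSE)
)

setMethod("show", "AnnotatedTree", function(object) {
  cat(sprintf("AnnotatedTree: MCC over %d taxa, log-score %.4f%s\n",
              length(object@tree$tip.label), object@score,
              if (object@tie) " (tie, earliest sampled tree kept)" else ""))
  if (nrow(object@summaries)) {
    has_age <- !all(is.na(object@summaries$median))
    cat(sprintf("  %d internal clades%s\n", nrow(object@summaries),
                if (has_age) ", ages annotated" else ""))
  }
})

#' MCC tree accessor
#' @param x an \code{AnnotatedTree}.
#' @return the \code{phylo} MCC tree.
#' @export
mccPhylo <- function(x) x@tree

#' Clade age/support summaries of an annotated tree
#' @param x an \code{AnnotatedTree}.
#' @return data.frame of per-clade summaries.
#' @export
cladeSummaries <- function(x) x@summaries

#' Configuration of the sticky-chain topology sampler
#'
#' The sticky chain is the package's oracle process: at each step the
#' chain stays at the current rooted topology with probability
#' \code{alpha} and otherwise regenerates from the stationary
#' distribution \code{pi} over all rooted binary topologies on the taxon
#' set. Its stationary law and autocorrelation time
#' \eqn{(1+\alpha)/(1-\alpha)} are exact, which makes every clade
#' probability and ESS computable in closed form.
#'
#' @slot taxa taxon labels (2..6, enumeration guard).
#' @slot pi stationary probabilities over the enumerated topologies
#'   (empty = draw from a symmetric Dirichlet(1) under the seed).
#' @slot alpha stickiness in \[0, 1).
#' @slot n chain length.
#' @slot seed RNG seed.
#'
#' @exportClass StickyChainConfig
setClass("StickyChainConfig",
  representation(taxa = "character", pi = "numeric", alpha = "numeric",
                 n = "integer", seed = "integer")
)

setValidity("StickyChainConfig", function(object) {
  msg <- character()
  k <- length(object@taxa)
  if (k < 2 || k > 6)
    msg <- c(msg, "taxa must number between 2 and 6 (enumeration guard)")
  if (length(object@pi) &&
      abs(sum(object@pi) - 1) > 1e-12)
    msg <- c(msg, "pi must sum to 1 within 1e-12")
  if (length(object@pi) && any(object@pi < 0))
    msg <- c(msg, "pi must be non-negative")
  if (object@alpha < 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in [0, 1)")
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StickyChainConfig
#'
#' @param taxa taxon labels (at most 6).
#' @param pi explicit stationary distribution over the enumerated rooted
#'   topologies, or \code{NULL} to draw one from Dirichlet(1) using
#'   \code{seed}.
#' @param alpha stickiness in \[0,1); the chain's autocorrelation time is
#'   (1+alpha)/(1-alpha).
#' @param n chain length.
#' @param seed RNG seed.
#' @return a \linkS4class{StickyChainConfig}.
#' @export
stickyChainConfig <- function(taxa, pi = NULL, alpha = 0, n = 1000L,
                              seed = 1L) {
  new("StickyChainConfig", taxa = taxa,
      pi = if (is.null(pi)) numeric() else pi,
      alpha = alpha, n = as.integer(n), seed = as.integer(seed))
}

#' Generative model configuration for dated trees and alignments
#'
#' Parameters of the birth-death + uncorrelated-lognormal-clock +
#' GTR+G+I generative model. Defaults follow the standard insect
#' mitochondrial calibration: clock mean 0.0115 substitutions/site/Myr
#' and a sharply concentrated among-site gamma (shape 11.1, six
#' categories).
#'
#' @slot nTaxa number of extant tips.
#' @slot birthRate speciation rate (events/Myr).
#' @slot relativeDeathRate extinction-to-speciation ratio in \[0, 1).
#' @slot ucldMean real-scale mean of per-branch clock rates
#'   (substitutions/site/Myr).
#' @slot ucldStdev log-scale standard deviation of branch rates (>= 0).
#' @slot gtrRates six relative exchangeabilities, order AC, AG, AT, CG,
#'   CT, GT.
#' @slot baseFreq equilibrium base frequencies (A, C, G, T), summing to 1.
#' @slot gammaShape among-site gamma shape.
#' @slot gammaCategories number of discrete gamma categories.
#' @slot pInv proportion of invariant sites in \[0, 1\].
#' @slot length alignment length (sites).
#' @slot seed RNG seed.
#'
#' @exportClass SeqSimConfig
setClass("SeqSimConfig",
  representation(
    nTaxa = "integer", birthRate = "numeric",
    relativeDeathRate = "numeric", ucldMean = "numeric",
    ucldStdev = "numeric", gtrRates = "numeric", baseFreq = "numeric",
    gammaShape = "numeric", gammaCategories = "integer", pInv = "numeric",
    length = "integer", seed = "integer"
  )
)

setValidity("SeqSimConfig", function(object) {
  msg <- character()
  if (object@nTaxa < 2) msg <- c(msg, "nTaxa must be >= 2")
  if (object@birthRate <= 0) msg <- c(msg, "birthRate must be > 0")
  if (object@relativeDeathRate < 0 || object@relativeDeathRate >= 1)
    msg <- c(msg, "relativeDeathRate must lie in [0, 1)")
  if (object@ucldMean <= 0) msg <- c(msg, "ucldMean must be > 0")
  if (object@ucldStdev < 0) msg <- c(msg, "ucldStdev must be >= 0")
  if (length(object@gtrRates) != 6 || any(object@gtrRates <= 0))
    msg <- c(msg, "gtrRates must be six positive exchangeabilities")
  if (length(object@baseFreq) != 4 ||
      abs(sum(object@baseFreq) - 1) > 1e-8 || any(object@baseFreq <= 0))
    msg <- c(msg, "baseFreq must be four positive values summing to 1")
  if (object@gammaShape <= 0) msg <- c(msg, "gammaShape must be > 0")
  if (object@gammaCategories < 1)
    msg <- c(msg, "gammaCategories must be >= 1")
  if (object@pInv < 0 || object@pInv > 1)
    msg <- c(msg, "pInv must lie in [0, 1]")
  if (object@length < 1) msg <- c(msg, "alignment length must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SeqSimConfig
#'
#' @param nTaxa number of extant tips.
#' @param birthRate speciation rate (events/Myr).
#' @param relativeDeathRate relative extinction rate in \[0,1).
#' @param ucldMean real-scale mean branch rate (substitutions/site/Myr);
#'   0.0115 is the standard arthropod mitochondrial rate, 0.004 the
#'   nuclear setting used for a comparable tree height.
#' @param ucldStdev log-scale stdev of branch rates (0 = strict clock).
#' @param gtrRates six relative exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param baseFreq equilibrium base frequencies (A, C, G, T).
#' @param gammaShape among-site gamma shape (default 11.1).
#' @param gammaCategories discrete gamma category count (default 6).
#' @param pInv proportion of invariant sites.
#' @param length alignment length in sites.
#' @param seed RNG seed.
#' @return a \linkS4class{SeqSimConfig}.
#' @examples
#' seqSimConfig(nTaxa = 5, length = 200)
#' @export
seqSimConfig <- function(nTaxa = 8L, birthRate = 0.3,
                         relativeDeathRate = 0, ucldMean = 0.0115,
                         ucldStdev = 0.3, gtrRates = rep(1, 6),
                         baseFreq = rep(0.25, 4), gammaShape = 11.1,
                         gammaCategories = 6L, pInv = 0, length = 658L,
                         seed = 1L) {
  new("SeqSimConfig", nTaxa = as.integer(nTaxa), birthRate = birthRate,
      relativeDeathRate = relativeDeathRate, ucldMean = ucldMean,
      ucldStdev = ucldStdev, gtrRates = gtrRates, baseFreq = baseFreq,
      gammaShape = gammaShape,
      gammaCategories = as.integer(gammaCategories), pInv = pInv,
      length = as.integer(length), seed = as.integer(seed))
}

#' Ground truth attached to synthetic data
#'
#' @slot trueTree the generating tree (with ages), if any.
#' @slot branchRates per-branch clock rates, if any.
#' @slot pi stationary topology probabilities of a sticky chain.
#' @slot topologyIds per-sample topology index of a sticky chain.
#' @slot act analytic autocorrelation time (1+alpha)/(1-alpha).
#' @slot taxa taxon labels (order matching the enumeration).
#'
#' @exportClass SimTruth
setClass("SimTruth",
  representation(
    trueTree = "ANY", branchRates = "numeric", pi = "numeric",
    topologyIds = "integer", act = "numeric", taxa = "character"
  ),
  prototype(trueTree = NULL, branchRates = numeric(), pi = numeric(),
            topologyIds = integer(), act = NA_real_, taxa = character())
)

setValidity("SimTruth", function(object) {
  if (!is.na(object@act) && object@act < 1)
    "autocorrelation time must be >= 1" else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:\n")
  if (length(object@pi))
    cat(sprintf("  sticky chain over %d topologies, ACT = %.3f\n",
                length(object@pi), object@act))
  if (!is.null(object@trueTree))
    cat(sprintf("  generating tree with %d tips\n",
                length(object@trueTree$tip.label)))
})

#' Per-group haplotype table
#'
#' @slot table data.frame with columns group, nSequences, nHaplotypes.
#' @slot members per group, a named list mapping each haplotype sequence
#'   string to the ids carrying it.
#'
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(table = "data.frame", members = "list")
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  for (g in names(object@members)) {
    m <- object@members[[g]]
    row <- object@table[object@table$group == g, ]
    if (nrow(row) != 1) { msg <- c(msg, "table/members mismatch"); next }
    if (row$nHaplotypes != length(m))
      msg <- c(msg, sprintf("group %s: haplotype count mismatch", g))
    if (row$nSequences != sum(lengths(m)))
      msg <- c(msg, sprintf("group %s: sequence count mismatch", g))
    if (length(m) > sum(lengths(m)))
      msg <- c(msg, sprintf("group %s: more haplotypes than sequences", g))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:\n")
  print(object@table, row.names = FALSE)
})

#' Fragment-length species classifier
#'
#' Maps diagnostic amplicon lengths (bp) to species labels, with an
#' optional matching tolerance. Entries whose lengths collide within the
#' tolerance are flagged at construction.
#'
#' @slot lengths integer fragment lengths (bp).
#' @slot labels species label per length.
#' @slot tolerance matching tolerance in bp (default 0).
#'
#' @exportClass LengthClassifier
setClass("LengthClassifier",
  representation(lengths = "integer", labels = "character",
                 tolerance = "integer")
)

setValidity("LengthClassifier", function(object) {
  msg <- character()
  if (any(object@lengths <= 0)) msg <- c(msg, "lengths must be positive")
  if (length(object@lengths) != length(object@labels))
    msg <- c(msg, "lengths and labels must align")
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LengthClassifier", function(object) {
  cat("LengthClassifier (tolerance", object@tolerance, "bp):\n")
  for (i in seq_along(object@lengths))
    cat(sprintf("  %d bp -> %s\n", object@lengths[i], object@labels[i]))
})
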