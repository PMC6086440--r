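# Effective-sample-size estimators: the Tracer-style scalar ESS, and the
# two topological ESS estimators built on the path distance — the
# pseudo-ESS (ESS of distances to random focal trees) and the
# approximate ESS (from the autocorrelation of topological distances).

#' Scalar effective sample size of a parameter trace
#'
#' \eqn{ESS = N / (1 + 2 \sum_{k=1}^{K} \hat\rho_k)} where
#' \eqn{\hat\rho_k} is the sample autocorrelation at lag k and the sum
#' is truncated at the first negative autocorrelation (capped at
#' \code{maxLag}). The result is clamped to \[1, N\].
#'
#' @param series numeric vector, length >= 10, non-constant.
#' @param maxLag truncation cap for the autocorrelation sum (default
#'   \code{min(N - 1, 2000)}, the standard desk-scale behaviour).
#' @return the effective sample size, in \[1, N\].
#' @examples
#' set.seed(1); scalarESS(rnorm(1000))  # close to 1000
#' @export
scalarESS <- function(series, maxLag = NULL) {
  n <- length(series)
  if (n < 10) stopInput("series too short for ESS (need >= 10 samples)")
  if (var(series) == 0)
    stopInput("zero-variance series: degenerate trace")
  if (is.null(maxLag)) maxLag <- min(n - 1L, 2000L)
  maxLag <- min(maxLag, n - 1L)
  rho <- as.numeric(acf(series, lag.max = maxLag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  firstNeg <- which(rho < 0)
  k <- if (length(firstNeg)) firstNeg[1] - 1L else length(rho)
  ess <- n / (1 + 2 * sum(rho[seq_len(k)]))
  min(max(ess, 1), n)
}

#' Topological pseudo-ESS of a tree trace
#'
#' For each of \code{nFocal} focal trees drawn uniformly (with
#' replacement, seeded) from the trace, the series of path distances
#' from every sampled tree to the focal tree is formed and its scalar
#' ESS computed. The per-replicate values and their median — the
#' reported ESS_topology, basis "P" — are returned.
#'
#' @param trace a \linkS4class{TreeTrace} with at least two distinct
#'   topologies.
#' @param nFocal number of focal-tree replicates (default 20).
#' @param seed RNG seed for focal-tree sampling.
#' @param unrooted use unrooted path counts (default FALSE).
#' @return list with \code{replicates} (numeric vector), \code{median},
#'   \code{seed}.
#' @export
pseudoTopoESS <- function(trace, nFocal = 20L, seed = 1L,
                          unrooted = FALSE) {
  n <- length(trace)
  idx <- traceTopologyIndex(trace)
  if (length(idx$trees) < 2)
    stopInput("single distinct topology: topological ESS is undefined")
  pathMat <- .topoPathMatrix(idx, unrooted)
  focal <- withSeed(seed, sample.int(n, nFocal, replace = TRUE))
  reps <- vapply(focal, function(f) {
    series <- .topoDistance(pathMat, idx$ids, rep(idx$ids[f], n))
    scalarESS(series)
  }, 0)
  list(replicates = reps, median = median(reps), seed = as.integer(seed))
}

#' Approximate topological ESS of a tree trace
#'
#' Let \eqn{\bar D(k)} be the mean path distance over all in-order pairs
#' of sampled trees at lag k, and \eqn{\bar D_\infty} the mean distance
#' over all unordered pairs of distinct samples. Because distances only
#' depend on the distinct topologies, \eqn{\bar D_\infty} is computed
#' exactly as a frequency-weighted sum whenever the distinct-topology
#' count allows it; traces with very many distinct topologies fall back
#' to an unbiased estimate from \code{nPairs} seeded random pairs (a
#' noisy \eqn{\bar D_\infty} would bias every lag term). The topological
#' autocorrelation is \eqn{\rho_{topo}(k) = \max(0, 1 - \bar D(k)/\bar
#' D_\infty)} and \eqn{ESS = N / (1 + 2\sum_k \rho_{topo}(k))}, the sum
#' truncated at the first k with \eqn{\rho_{topo}(k) = 0}; clamped to
#' \[1, N\]. This is ESS_topology, basis "A".
#'
#' @param trace a \linkS4class{TreeTrace} with >= 2 distinct topologies.
#' @param maxLag largest lag examined (default \code{min(N - 1, 100)}).
#' @param nPairs random pairs used for \eqn{\bar D_\infty} when the
#'   exact weighted mean is out of reach (default 500).
#' @param seed RNG seed for the random pairs (unused on the exact path).
#' @param unrooted use unrooted path counts (default FALSE).
#' @return the approximate topological ESS, in \[1, N\].
#' @export
approxTopoESS <- function(trace, maxLag = NULL, nPairs = 500L, seed = 1L,
                          unrooted = FALSE) {
  n <- length(trace)
  idx <- traceTopologyIndex(trace)
  if (length(idx$trees) < 2)
    stopInput("single distinct topology: topological ESS is undefined")
  if (is.null(maxLag)) maxLag <- min(n - 1L, 100L)
  maxLag <- min(maxLag, n - 1L)
  if (maxLag == 0) return(n)
  pathMat <- .topoPathMatrix(idx, unrooted)
  ids <- idx$ids

  u <- length(idx$trees)
  if (u * u <= 4e6) {
    # exact mean over all unordered distinct-sample pairs: distances
    # depend only on the distinct topologies, so weight the U x U
    # distance matrix by topology counts
    D <- as.matrix(stats::dist(t(pathMat)))
    cnt <- tabulate(ids, nbins = u)
    # denominator counts all ordered pairs of distinct samples; pairs of
    # distinct samples sharing a topology contribute distance 0
    dInf <- as.numeric(cnt %*% D %*% cnt) / (n^2 - n)
  } else {
    pairs <- withSeed(seed, {
      i <- sample.int(n, nPairs, replace = TRUE)
      j <- sample.int(n - 1L, nPairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)   # uniform unordered distinct pairs
      cbind(i, j)
    })
    dInf <- mean(.topoDistance(pathMat, ids[pairs[, 1]],
                               ids[pairs[, 2]]))
  }
  if (dInf == 0)
    stopInput("all sampled trees identical: approximate ESS undefined")

  rho <- numeric(maxLag)
  for (k in seq_len(maxLag)) {
    dk <- mean(.topoDistance(pathMat, ids[seq_len(n - k)],
                             ids[seq.int(k + 1L, n)]))
    rho[k] <- max(0, 1 - dk / dInf)
    if (rho[k] == 0) { rho <- rho[seq_len(k)]; break }
  }
  if (rho[length(rho)] == 0) rho <- rho[-length(rho)]
  ess <- n / (1 + 2 * sum(rho))
  min(max(ess, 1), n)
}

#' Build a full ESS report for a tree trace
#'
#' Combines the scalar ESS of any named parameter traces with the two
#' topological ESS estimates for the tree trace itself.
#'
#' @param trace a \linkS4class{TreeTrace}.
#' @param scalarTraces named list (or data.frame) of numeric parameter
#'   traces, e.g. read with \code{\link{readTraceLog}}.
#' @param config a \linkS4class{PipelineConfig} supplying the seed and
#'   the gate threshold.
#' @param nFocal focal-tree replicates for the pseudo-ESS.
#' @param maxLag,nPairs approximate-ESS knobs (see
#'   \code{\link{approxTopoESS}}).
#' @param unrooted use unrooted path counts.
#' @return an \linkS4class{ESSReport}.
#' @export
essReport <- function(trace, scalarTraces = list(),
                      config = pipelineConfig(), nFocal = 20L,
                      maxLag = NULL, nPairs = 500L, unrooted = FALSE) {
  scal <- vapply(scalarTraces, scalarESS, 0)
  if (length(scal)) names(scal) <- names(scalarTraces)
  ps <- pseudoTopoESS(trace, nFocal = nFocal,
                      seed = deriveSeed(config@seed, "pseudo"),
                      unrooted = unrooted)
  ap <- approxTopoESS(trace, maxLag = maxLag, nPairs = nPairs,
                      seed = deriveSeed(config@seed, "approx"),
                      unrooted = unrooted)
  new("ESSReport", n = length(trace), scalar = scal,
      pseudoReplicates = ps$replicates, pseudo = ps$median, approx = ap,
      threshold = config@essThreshold, seed = config@seed)
}

#' Convergence gate on an ESS report
#'
#' Flags every ESS entry against a threshold; the overall gate passes
#' iff all entries exceed it.
#'
#' @param report an \linkS4class{ESSReport}.
#' @param threshold gate value (default: the report's own threshold,
#'   conventionally 200).
#' @return data.frame with columns entry, ess, pass; attribute
#'   \code{overall} is the conjunction.
#' @export
essGate <- function(report, threshold = report@threshold) {
  vals <- c(report@scalar,
            `topological (P)` = report@pseudo,
            `topological (A)` = report@approx)
  vals <- vals[!is.na(vals)]
  out <- data.frame(entry = names(vals), ess = as.numeric(vals),
                    pass = as.numeric(vals) > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "overall") <- all(out$pass)
  out
}

#' Read a tab-separated sampler log of scalar parameter traces
#'
#' Expects a header row of parameter names and one row per retained
#' sample, with a leading state/generation column. Comment lines
#' starting with "#" are skipped.
#'
#' @param path path to the log file.
#' @param burnin leading fraction of rows to discard (default 0).
#' @return data.frame of numeric parameter traces (state column
#'   retained as \code{state}).
#' @export
readTraceLog <- function(path, burnin = 0) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  if (!ncol(df)) stopInput("empty trace log: %s", path)
  names(df)[1] <- "state"
  drop <- floor(burnin * nrow(df))
  if (drop >= nrow(df)) stopInput("burn-in discards all samples")
  df[seq.int(drop + 1L, nrow(df)), , drop = FALSE]
}

#' Serialize an ESS report to JSON
#'
#' @param report an \linkS4class{ESSReport}.
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
essReportToJson <- function(report, path = NULL) {
  x <- list(
    n = report@n,
    scalar = as.list(report@scalar),
    pseudo = list(median = report@pseudo,
                  replicates = report@pseudoReplicates,
                  nReplicates = length(report@pseudoReplicates),
                  seed = report@seed),
    approx = report@approx,
    threshold = report@threshold,
    gate = attr(essGate(report), "overall")
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
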