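# Posterior summarisation: highest-posterior-density intervals, the
# maximum-clade-credibility tree, posterior median node ages, and
# divergence-time report rows.

#' Highest-posterior-density interval
#'
#' The smallest-width window of sorted samples containing
#' \eqn{m = \lceil level \cdot n \rceil} points; ties are broken by the
#' earliest window.
#'
#' @param samples numeric vector, length >= 1.
#' @param level probability mass in (0, 1\] (default 0.95).
#' @return numeric (lower, upper).
#' @examples
#' hpdInterval(1:100, 0.95)  # c(1, 95)
#' @export
hpdInterval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n == 0) stopInput("empty sample: HPD undefined")
  if (n == 1) return(c(samples, samples))
  xs <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(xs[1], xs[n]))
  lo <- seq_len(n - m + 1L)
  widths <- xs[lo + m - 1L] - xs[lo]
  i <- which.min(widths)   # which.min takes the earliest tie
  c(xs[i], xs[i + m - 1L])
}

#' Central credible interval (alternative to the HPD)
#'
#' Equal-tail interval at the given mass; offered because published
#' "95\% CI" labels do not always distinguish the two conventions.
#'
#' @param samples numeric vector.
#' @param level probability mass (default 0.95).
#' @return numeric (lower, upper).
#' @export
centralInterval <- function(samples, level = 0.95) {
  a <- (1 - level) / 2
  as.numeric(quantile(samples, c(a, 1 - a), names = FALSE, type = 7))
}

# Clade frequency table of a trace: named numeric (key -> frequency),
# counting every internal clade (root included) once per tree.
.cladeFrequencies <- function(trace) {
  idx <- traceTopologyIndex(trace)
  counts <- tabulate(idx$ids, nbins = length(idx$trees))
  tab <- new.env(parent = emptyenv())
  for (u in seq_along(idx$trees)) {
    for (cl in extractClades(idx$trees[[u]])) {
      key <- cladeKey(cl)
      prev <- if (is.null(tab[[key]])) 0 else tab[[key]]
      tab[[key]] <- prev + counts[u]
    }
  }
  keys <- ls(tab)
  setNames(vapply(keys, function(k) tab[[k]], 0) / length(trace), keys)
}

#' Maximum-clade-credibility tree of a posterior sample
#'
#' Each sampled tree is scored by the sum over its non-trivial internal
#' clades (root and leaves excluded) of the natural log of the clade's
#' posterior frequency; the highest-scoring sampled tree is returned
#' (ties broken by the earliest tree in the trace, and flagged). The
#' candidate set is the sampled trees only — no synthesised consensus.
#'
#' @param trace a non-empty \linkS4class{TreeTrace}.
#' @return an \linkS4class{AnnotatedTree} whose summaries carry per-clade
#'   support (clade frequency) and tree counts; ages are NA until
#'   \code{\link{annotateAges}} is applied.
#' @examples
#' tr <- treeTrace(lapply(
#'   c("((A,B),C);", "((A,B),C);", "((A,C),B);"), parseNewick))
#' mccPhylo(mccTree(tr))
#' @export
mccTree <- function(trace) {
  n <- length(trace)
  freqs <- .cladeFrequencies(trace)
  idx <- traceTopologyIndex(trace)
  rootKey <- cladeKey(trace@taxa)
  scoreOf <- vapply(seq_along(idx$trees), function(u) {
    keys <- vapply(extractClades(idx$trees[[u]]), cladeKey, "")
    keys <- keys[keys != rootKey]
    sum(log(freqs[keys]))
  }, 0)
  best <- max(scoreOf)
  bestIds <- which(scoreOf >= best - 1e-12)
  tie <- length(bestIds) > 1
  winner <- min(which(idx$ids %in% bestIds))
  tree <- trace@trees[[winner]]

  clades <- extractClades(tree)
  keys <- vapply(clades, cladeKey, "")
  summaries <- data.frame(
    clade = keys,
    size = lengths(clades),
    support = as.numeric(freqs[keys]),
    count = as.integer(round(freqs[keys] * n)),
    median = NA_real_, lower = NA_real_, upper = NA_real_,
    level = NA_real_, lowSupport = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (tie)
    message("MCC score tie between distinct topologies; ",
            "earliest sampled tree kept")
  new("AnnotatedTree", tree = tree, summaries = summaries,
      score = best, tie = tie)
}

#' Attach posterior node-age summaries to an MCC tree
#'
#' For each internal clade of the MCC tree, the ages of the matching
#' node are collected from every trace tree containing that clade (trees
#' lacking the clade contribute nothing — no common-ancestor fallback),
#' and summarised by the posterior median and the HPD interval. Child
#' medians exceeding their parent's are reported as-is with a warning,
#' never clipped.
#'
#' @param mcc an \linkS4class{AnnotatedTree} from \code{\link{mccTree}}.
#' @param trace the \linkS4class{TreeTrace} the MCC tree came from;
#'   trees must be ultrametric so ages are computable.
#' @param level HPD mass (default 0.95).
#' @param interval "hpd" (default) or "central".
#' @param supportFloor clades with support below this keep their
#'   summaries but are flagged (default 0.5).
#' @return the annotated \linkS4class{AnnotatedTree}.
#' @export
annotateAges <- function(mcc, trace, level = 0.95, interval = "hpd",
                         supportFloor = 0.5) {
  interval <- match.arg(interval, c("hpd", "central"))
  keys <- mcc@summaries$clade
  ageSamples <- setNames(vector("list", length(keys)), keys)
  for (tr in trace@trees) {
    ages <- nodeAges(tr)
    ntip <- length(tr$tip.label)
    tkeys <- vapply(extractClades(tr), cladeKey, "")
    hit <- match(tkeys, keys)
    for (j in which(!is.na(hit))) {
      k <- keys[hit[j]]
      ageSamples[[k]] <- c(ageSamples[[k]], ages[ntip + j])
    }
  }
  s <- mcc@summaries
  for (r in seq_len(nrow(s))) {
    a <- as.numeric(ageSamples[[s$clade[r]]])
    if (!length(a))
      stop("internal error: MCC clade absent from every sampled tree")
    s$median[r] <- median(a)
    ci <- if (interval == "hpd") hpdInterval(a, level)
          else centralInterval(a, level)
    s$lower[r] <- ci[1]; s$upper[r] <- ci[2]
    s$level[r] <- level
    s$lowSupport[r] <- s$support[r] < supportFloor
  }
  # flag (not clip) age inversions between nested clades
  parentKeys <- .parentCladeKeys(mcc@tree)
  inv <- which(!is.na(parentKeys) &
                 s$median > s$median[match(parentKeys, s$clade)] + 1e-12)
  if (length(inv))
    warning(sprintf(
      "%d clade(s) have a median age exceeding their parent's; %s",
      length(inv), "reported as-is"), call. = FALSE)
  new("AnnotatedTree", tree = mcc@tree, summaries = s, score = mcc@score,
      tie = mcc@tie)
}

# For each internal node (in summaries order), the clade key of its
# parent internal node, NA for the root.
.parentCladeKeys <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- descendantLeafSets(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(tree$Nnode), function(j) {
    node <- ntip + j
    if (parent[node] == 0L) NA_character_
    else cladeKey(sets[[parent[node]]])
  }, "")
}

#' Divergence-time report rows for named taxon pairs
#'
#' Resolves each named taxon set to its most recent common ancestor in
#' the MCC tree and reports that node's age summary. Sets that are not
#' monophyletic in the MCC tree still resolve (to the MRCA) but are
#' flagged.
#'
#' @param annotated an age-annotated \linkS4class{AnnotatedTree}.
#' @param namedPairs named list of taxon sets (character vectors).
#' @return data.frame with columns label, median, lower, upper, support,
#'   monophyletic; ages carry the trace's time units.
#' @export
divergenceTable <- function(annotated, namedPairs) {
  tree <- annotated@tree
  s <- annotated@summaries
  if (all(is.na(s$median)))
    stopInput("annotate ages first (annotateAges) before tabulating")
  sets <- descendantLeafSets(tree)
  ntip <- length(tree$tip.label)
  rows <- lapply(names(namedPairs), function(lab) {
    taxa <- namedPairs[[lab]]
    unknown <- setdiff(taxa, tree$tip.label)
    if (length(unknown))
      stopInput("pair '%s' names unknown taxa: %s", lab,
                paste(unknown, collapse = ", "))
    node <- if (length(taxa) == 1) match(taxa, tree$tip.label)
            else ape::getMRCA(tree, taxa)
    key <- cladeKey(sets[[node]])
    mono <- setequal(sets[[node]], taxa)
    r <- s[s$clade == key, , drop = FALSE]
    data.frame(label = lab, median = r$median, lower = r$lower,
               upper = r$upper, support = r$support,
               monophyletic = mono, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a divergence table the way field reports print it
#'
#' Two-decimal medians with the interval in parentheses, e.g.
#' \code{"12.87 (95\% HPD: 11.11-15.75)"}.
#'
#' @param div a data.frame from \code{\link{divergenceTable}}.
#' @param level interval level for the label (default 0.95).
#' @return character vector, one formatted row per entry.
#' @export
formatDivergenceRows <- function(div, level = 0.95) {
  sprintf("%s: %.2f (%d%% HPD: %.2f-%.2f)%s",
          div$label, div$median, round(100 * level), div$lower,
          div$upper,
          ifelse(div$monophyletic, "", " [non-monophyletic: MRCA used]"))
}

#' Write an age-annotated MCC tree as NEXUS
#'
#' Embeds \code{[&posterior=..,age_median=..,age_hpd={..,..}]} comments
#' on internal nodes, readable by standard tree viewers.
#'
#' @param annotated an age-annotated \linkS4class{AnnotatedTree}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMccNexus <- function(annotated, path) {
  tree <- annotated@tree
  ntip <- length(tree$tip.label)
  s <- annotated@summaries
  ann <- character(ntip + tree$Nnode)
  keys <- vapply(extractClades(tree), cladeKey, "")
  for (j in seq_along(keys)) {
    r <- s[s$clade == keys[j], , drop = FALSE]
    if (!nrow(r)) next
    ann[ntip + j] <- if (is.na(r$median))
      sprintf("posterior=%.6g", r$support)
    else
      sprintf("posterior=%.6g,age_median=%.6g,age_hpd={%.6g,%.6g}",
              r$support, r$median, r$lower, r$upper)
  }
  writeAnnotatedNexus(tree, path, annotations = ann, name = "MCC")
}
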