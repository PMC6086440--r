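# NEXUS trees-block I/O in the dialect emitted by common Bayesian
# samplers: a TREES block, an optional Translate table, and per-node
# "[&...]" metadata comments on the tree statements. DATA/CHARACTERS
# blocks are out of scope.

#' Read a NEXUS trees file into a TreeTrace
#'
#' Reads the TREES block of a NEXUS file, resolves Translate indices to
#' taxon labels, strips (or retains) \code{[&...]} metadata comments and
#' discards the leading burn-in fraction of the sampled trees. Burn-in
#' applies to the retained (post-thinning) samples in the file, which is
#' the convention for thinned sampler output.
#'
#' @param path path to a NEXUS file containing a TREES block.
#' @param config a \linkS4class{PipelineConfig}; its \code{burnin}
#'   fraction is applied unless overridden.
#' @param burnin optional burn-in fraction overriding the config.
#' @param keepAnnotations retain \code{[&...]} node comments as tree
#'   attributes (default FALSE: stripped).
#' @return a \linkS4class{TreeTrace}. Sample indices are taken from
#'   trailing integers in tree names (e.g. \code{STATE_1000}) when
#'   present, otherwise 1..N.
#' @examples
#' f <- tempfile(fileext = ".nex")
#' writeLines(c("#NEXUS", "begin trees;",
#'   "translate", "  1 A,", "  2 B,", "  3 C;",
#'   "tree STATE_0 = [&R] ((1:1,2:1):1,3:2);",
#'   "tree STATE_1000 = [&R] ((1:1,3:1):1,2:2);",
#'   "end;"), f)
#' readNexusTrees(f, burnin = 0)
#' @export
readNexusTrees <- function(path, config = pipelineConfig(), burnin = NULL,
                           keepAnnotations = FALSE) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  if (is.null(burnin)) burnin <- config@burnin
  if (burnin < 0 || burnin >= 1) stopInput("burn-in must lie in [0, 1)")
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")

  m <- regexpr("(?i)begin\\s+trees\\s*;", txt, perl = TRUE)
  if (m < 0) stopInput("no TREES block found in %s", path)
  body <- substr(txt, m + attr(m, "match.length"), nchar(txt))
  endm <- regexpr("(?i)\\bend\\s*;", body, perl = TRUE)
  if (endm > 0) body <- substr(body, 1, endm - 1)

  # statements are ';'-terminated, but ';' may occur inside comments
  stmts <- character(); buf <- character(); depth <- 0L
  for (ch in strsplit(body, "", fixed = TRUE)[[1]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- max(0L, depth - 1L)
    buf <- c(buf, ch)
    if (ch == ";" && depth == 0L) {
      stmts <- c(stmts, trimws(paste(buf, collapse = "")))
      buf <- character()
    }
  }

  translate <- character()
  treeStrings <- character()
  treeNames <- character()
  for (s in stmts) {
    if (grepl("^(?i)translate\\b", s, perl = TRUE)) {
      tbody <- sub("^(?i)translate\\s*", "", s, perl = TRUE)
      tbody <- sub(";\\s*$", "", tbody)
      entries <- strsplit(tbody, ",")[[1]]
      for (e in entries) {
        e <- trimws(e)
        if (!nzchar(e)) next
        parts <- regmatches(e, regexec(
          "^(\\S+)\\s+('(?:[^']|'')*'|\\S+)$", e))[[1]]
        if (length(parts) != 3)
          stopInput("malformed translate entry: '%s'", e)
        lab <- parts[3]
        if (startsWith(lab, "'"))
          lab <- gsub("''", "'", substr(lab, 2, nchar(lab) - 1))
        translate[parts[2]] <- lab
      }
    } else if (grepl("^(?i)tree\\b", s, perl = TRUE)) {
      mm <- regexec("^(?i)tree\\s+(\\S+)\\s*=\\s*(.*)$", s, perl = TRUE)
      parts <- regmatches(s, mm)[[1]]
      if (length(parts) != 3) stopInput("malformed tree statement")
      treeNames <- c(treeNames, parts[2])
      # drop leading rooting token [&R]/[&U] and any pre-tree comments
      tstr <- sub("^\\s*(\\[[^]]*\\]\\s*)*", "", parts[3], perl = TRUE)
      treeStrings <- c(treeStrings, tstr)
    }
  }
  if (!length(treeStrings))
    stopInput("TREES block of %s contains no tree statements", path)

  total <- length(treeStrings)
  drop <- floor(burnin * total)
  if (drop >= total)
    stopInput("burn-in %.2f discards all %d trees", burnin, total)
  keep <- seq.int(drop + 1L, total)

  trees <- vector("list", length(keep))
  taxa <- NULL
  for (j in seq_along(keep)) {
    tr <- parseNewick(treeStrings[keep[j]],
                      keepAnnotations = keepAnnotations)
    if (length(translate)) {
      unknown <- setdiff(tr$tip.label, names(translate))
      # files may mix translated indices and literal labels; only
      # pure-index tip sets are remapped
      if (all(grepl("^[0-9]+$", tr$tip.label))) {
        if (length(unknown))
          stopInput("translate table has no mapping for: %s",
                    paste(unknown, collapse = ", "))
        tr$tip.label <- unname(translate[tr$tip.label])
      }
    }
    if (is.null(taxa)) taxa <- sort(tr$tip.label)
    else if (!identical(sort(tr$tip.label), taxa))
      stopInput("tree %d has a different taxon set than the first tree",
                keep[j])
    trees[[j]] <- tr
  }

  idx <- suppressWarnings(
    as.integer(sub("^.*?([0-9]+)$", "\\1", treeNames[keep])))
  if (anyNA(idx) || any(diff(idx) <= 0)) idx <- seq_along(keep)
  new("TreeTrace", trees = trees, sampleIndex = idx, taxa = taxa,
      burnin = burnin, source = path)
}

#' Write a tree (optionally annotated) as a NEXUS file
#'
#' Produces a minimal NEXUS trees file with a Translate table and a
#' single tree statement; per-node annotation strings are embedded as
#' \code{[&...]} comments readable by standard tree viewers.
#'
#' @param tree a \code{phylo} tree.
#' @param path output file path.
#' @param annotations optional character vector of per-node annotation
#'   bodies (indexed by node id; e.g. \code{"median=1.5"}).
#' @param name tree name used in the tree statement.
#' @return invisibly, the path.
#' @export
writeAnnotatedNexus <- function(tree, path, annotations = NULL,
                                name = "TREE1") {
  labs <- sort(tree$tip.label)
  tr2 <- tree
  # zero-padded translate indices keep lexicographic child ordering
  # aligned with the numeric translate table
  tr2$tip.label <- sprintf(paste0("%0", nchar(length(labs)), "d"),
                           match(tree$tip.label, labs))
  nwk <- writeNewick(tr2, annotations = annotations)
  nwk <- gsub("(?<=[(,])0+(?=[1-9])", "", nwk, perl = TRUE)
  out <- c(
    "#NEXUS",
    "begin trees;",
    "\ttranslate",
    paste0("\t\t", seq_along(labs), " ",
           vapply(labs, quoteLabel, ""),
           c(rep(",", length(labs) - 1), ";")),
    paste0("tree ", name, " = [&R] ", nwk),
    "end;")
  writeLines(out, path)
  invisible(path)
}

#' Write a whole tree trace as a NEXUS trees file
#'
#' The inverse of \code{\link{readNexusTrees}}: a Translate table plus
#' one canonical tree statement per sampled tree, named by sample index
#' (\code{STATE_<i>}).
#'
#' @param trace a \linkS4class{TreeTrace}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNexusTrace <- function(trace, path) {
  labs <- trace@taxa
  width <- nchar(length(labs))
  lines <- c("#NEXUS", "begin trees;", "\ttranslate",
             paste0("\t\t", seq_along(labs), " ",
                    vapply(labs, quoteLabel, ""),
                    c(rep(",", length(labs) - 1), ";")))
  for (i in seq_along(trace@trees)) {
    tr <- trace@trees[[i]]
    tr$tip.label <- sprintf(paste0("%0", width, "d"),
                            match(tr$tip.label, labs))
    nwk <- writeNewick(tr)
    nwk <- gsub("(?<=[(,])0+(?=[1-9])", "", nwk, perl = TRUE)
    lines <- c(lines, paste0("tree STATE_", trace@sampleIndex[i],
                             " = [&R] ", nwk))
  }
  writeLines(c(lines, "end;"), path)
  invisible(path)
}
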