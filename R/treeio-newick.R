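#' Parse a Newick tree string
#'
#' A recursive-descent parser for rooted Newick trees that reports the
#' character position of any syntax error, keeps underscores in labels
#' verbatim (sample ids such as \code{GY018_borb} are common), supports
#' quoted labels, polytomies, and optional \code{[&...]} metadata
#' comments as written by Bayesian tree samplers.
#'
#' Branch lengths absent from the input are recorded as missing
#' (\code{NA}), never as zero; operations that need ages reject trees
#' with missing lengths.
#'
#' @param text a Newick string terminated by \code{";"}.
#' @param keepAnnotations if TRUE, \code{[&...]} comments are attached to
#'   their nodes as an \code{annotations} attribute (character vector
#'   indexed by node id); if FALSE they are discarded.
#' @return a rooted \code{ape} \code{phylo} object. Tips are numbered in
#'   order of appearance; internal nodes in preorder from the root.
#' @examples
#' tr <- parseNewick("((A:1.0,B:1.0):1.0,C:2.0);")
#' ape::Ntip(tr)
#' @export
parseNewick <- function(text, keepAnnotations = FALSE) {
  if (length(text) != 1 || !nzchar(trimws(text)))
    stopInput("empty Newick input")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 1L
  nmax <- length(chars)

  peek <- function() if (pos <= nmax) chars[pos] else ""
  fail <- function(what) {
    stopInput("Newick parse error at character %d: %s", pos, what)
  }
  skipWs <- function() {
    while (pos <= nmax && grepl("^[[:space:]]$", chars[pos]))
      pos <<- pos + 1L
  }
  readComment <- function() {
    # assumes chars[pos] == "["; comments may nest
    start <- pos
    depth <- 0L
    repeat {
      if (pos > nmax) { pos <<- start; fail("unterminated comment '['") }
      if (chars[pos] == "[") depth <- depth + 1L
      if (chars[pos] == "]") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
      pos <<- pos + 1L
    }
    com <- paste(chars[(start + 1L):(pos - 1L)], collapse = "")
    pos <<- pos + 1L
    com
  }
  skipComments <- function() {
    skipWs()
    out <- character()
    while (peek() == "[") {
      out <- c(out, readComment())
      skipWs()
    }
    out
  }
  readLabel <- function() {
    skipWs()
    if (peek() == "'") {
      pos <<- pos + 1L
      lab <- character()
      repeat {
        if (pos > nmax) fail("unterminated quoted label")
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= nmax && chars[pos + 1L] == "'") {
            lab <- c(lab, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { lab <- c(lab, ch); pos <<- pos + 1L }
      }
      return(paste(lab, collapse = ""))
    }
    lab <- character()
    while (pos <= nmax &&
           !chars[pos] %in% c("(", ")", ",", ":", ";", "[", "]") &&
           !grepl("^[[:space:]]$", chars[pos])) {
      lab <- c(lab, chars[pos]); pos <<- pos + 1L
    }
    paste(lab, collapse = "")
  }
  readNumber <- function() {
    skipWs()
    num <- character()
    while (pos <= nmax && grepl("^[-+0-9.eE]$", chars[pos])) {
      num <- c(num, chars[pos]); pos <<- pos + 1L
    }
    if (!length(num)) fail("expected a branch length")
    val <- suppressWarnings(as.numeric(paste(num, collapse = "")))
    if (is.na(val)) fail(sprintf("malformed number '%s'",
                                 paste(num, collapse = "")))
    val
  }

  # node store
  labels <- character(); lens <- numeric(); annots <- character()
  children <- list()
  newNode <- function() {
    k <- length(labels) + 1L
    labels[k] <<- ""; lens[k] <<- NA_real_; annots[k] <<- ""
    children[[k]] <<- integer()
    k
  }

  parseSubtree <- function() {
    skipComments()
    if (peek() == "(") {
      id <- newNode()
      pos <<- pos + 1L
      repeat {
        ch <- parseSubtree()
        children[[id]] <<- c(children[[id]], ch)
        skipComments()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      labels[id] <<- readLabel()
    } else {
      id <- newNode()
      lab <- readLabel()
      if (!nzchar(lab)) fail("expected a taxon label")
      labels[id] <<- lab
    }
    com <- skipComments()
    if (length(com)) annots[id] <<- paste(com, collapse = ";")
    if (peek() == ":") {
      pos <<- pos + 1L
      com <- skipComments()
      if (length(com) && !nzchar(annots[id]))
        annots[id] <<- paste(com, collapse = ";")
      lens[id] <<- readNumber()
      skipComments()
    }
    id
  }

  skipComments()
  rootId <- parseSubtree()
  skipComments()
  if (peek() != ";") fail("expected ';' terminating the tree")
  pos <- pos + 1L
  skipWs()
  if (pos <= nmax)
    fail("trailing characters after ';'")

  isLeaf <- lengths(children) == 0L
  if (isLeaf[rootId]) {
    # single-leaf tree: represent as root above one tip
    tipId <- rootId
    rootId <- newNode()
    children[[rootId]] <- tipId
    isLeaf <- lengths(children) == 0L
    if (is.na(lens[tipId])) lens[tipId] <- 0
  }
  tipOrder <- which(isLeaf)
  tipLabels <- labels[tipOrder]
  if (any(!nzchar(tipLabels))) stopInput("tree has an unlabelled leaf")
  dup <- unique(tipLabels[duplicated(tipLabels)])
  if (length(dup))
    stopInput("duplicate leaf labels: %s", paste(dup, collapse = ", "))

  ntip <- length(tipOrder)
  nint <- sum(!isLeaf)
  newId <- integer(length(labels))
  newId[tipOrder] <- seq_len(ntip)
  # internal nodes in preorder from root
  ctr <- ntip
  assignPre <- function(id) {
    if (isLeaf[id]) return(invisible())
    ctr <<- ctr + 1L
    newId[id] <<- ctr
    for (ch in children[[id]]) assignPre(ch)
  }
  assignPre(rootId)

  edge <- matrix(0L, nrow = ntip + nint - 1L, ncol = 2L)
  elen <- numeric(nrow(edge))
  k <- 0L
  emit <- function(id) {
    for (ch in children[[id]]) {
      k <<- k + 1L
      edge[k, ] <<- c(newId[id], newId[ch])
      elen[k] <<- lens[ch]
      emit(ch)
    }
  }
  emit(rootId)

  tree <- list(edge = edge, edge.length = elen, tip.label = tipLabels,
               Nnode = nint)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  nodeLabs <- labels[!isLeaf][order(newId[!isLeaf])]
  if (any(nzchar(nodeLabs))) tree$node.label <- nodeLabs
  if (all(is.na(tree$edge.length))) tree$edge.length <- NULL
  if (keepAnnotations) {
    ann <- character(ntip + nint)
    ann[newId] <- annots
    attr(tree, "annotations") <- ann
  }
  tree
}

# Format a branch length for Newick output (round-trip safe).
formatBrlen <- function(x) {
  if (is.null(x) || is.na(x)) return("")
  paste0(":", sprintf("%.15g", x))
}

quoteLabel <- function(lab) {
  if (grepl("[][(),:;']|\\s", lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

#' Write a tree as a canonical Newick string
#'
#' Children of every node are emitted ordered by their smallest
#' descendant leaf label, so two trees with the same rooted topology and
#' branch lengths produce the same string regardless of input rotation.
#'
#' @param tree a \code{phylo} tree.
#' @param annotations optional character vector of per-node annotation
#'   strings (indexed by node id, empty string = none); each non-empty
#'   entry is embedded as a \code{[&...]} comment on its node.
#' @return a Newick string terminated by \code{";"}.
#' @examples
#' writeNewick(parseNewick("(B:1,A:1);"))  # children reordered: A first
#' @export
writeNewick <- function(tree, annotations = NULL) {
  kids <- childList(tree)
  labs <- tree$tip.label
  brl <- tree$edge.length
  edgeOf <- integer(length(kids))
  edgeOf[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lenOf <- function(node) {
    if (is.null(brl) || edgeOf[node] == 0L) NA_real_ else brl[edgeOf[node]]
  }
  annOf <- function(node) {
    if (is.null(annotations) || node > length(annotations) ||
        !nzchar(annotations[node])) ""
    else paste0("[&", sub("^&", "", annotations[node]), "]")
  }
  rec <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch) || !length(ch)) {
      return(list(str = paste0(quoteLabel(labs[node]), annOf(node),
                               formatBrlen(lenOf(node))),
                  min = labs[node]))
    }
    parts <- lapply(ch, rec)
    mins <- vapply(parts, function(p) p$min, "")
    o <- order(mins)
    body <- paste(vapply(parts[o], function(p) p$str, ""), collapse = ",")
    list(str = paste0("(", body, ")", annOf(node),
                      if (node == rootNode(tree)) "" else
                        formatBrlen(lenOf(node))),
         min = mins[o[1]])
  }
  paste0(rec(rootNode(tree))$str, ";")
}
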