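# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps all package randomness behind
# explicit seeds without touching the global stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying below
# 2^31. Deterministic and collision-poor enough for the handful of
# streams used here.
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Children of each node as an adjacency list, indexed by phylo node id.
childList <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

rootNode <- function(tree) {
  length(tree$tip.label) + 1L
}

# Descendant leaf-label set per node, as a list indexed by node id.
# Postorder accumulation; labels kept sorted so set keys are canonical.
descendantLeafSets <- function(tree) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  sets <- vector("list", n)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

cladeKey <- function(taxa) paste(sort(taxa), collapse = "\t")

# Canonical label-only string of a rooted topology: children ordered by
# their smallest descendant leaf label, branch lengths ignored. Two trees
# share this string iff they have the same rooted topology.
canonicalTopologyKey <- function(tree) {
  kids <- childList(tree)
  labs <- tree$tip.label
  rec <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(list(key = labs[node], min = labs[node]))
    parts <- lapply(ch, rec)
    mins <- vapply(parts, function(p) p$min, "")
    o <- order(mins)
    list(key = paste0("(", paste(vapply(parts[o], function(p) p$key, ""),
                                 collapse = ","), ")"),
         min = mins[o[1]])
  }
  rec(rootNode(tree))$key
}

# Map each tree of a trace to an index over its distinct topologies.
# Returns ids (integer per tree) and one representative phylo per
# distinct topology. Used to make per-trace computations O(#distinct).
traceTopologyIndex <- function(trace) {
  keys <- vapply(trace@trees, canonicalTopologyKey, "")
  uk <- unique(keys)
  ids <- match(keys, uk)
  reps <- trace@trees[match(uk, keys)]
  list(ids = ids, trees = reps, keys = uk)
}

stopInput <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
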