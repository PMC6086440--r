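# Shared fixture builders; everything is generated in code.

ptree <- function(txt) parseNewick(txt)

# A trace built from newick strings (unit sample spacing).
traceFrom <- function(...) {
  treeTrace(lapply(c(...), parseNewick))
}

# Random rooted topology on n taxa with branch lengths, via ape.
randomTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- LETTERS[seq_len(n)]
  tr
}

# Small NEXUS trees file; returns its path.
writeToyNexus <- function(nTrees = 10, dir = tempdir()) {
  path <- tempfile("toy", tmpdir = dir, fileext = ".nex")
  topos <- c("((1:1,2:1):1,3:2);", "((1:1,3:1):1,2:2);",
             "((2:1,3:1):1,1:2);")
  lines <- c("#NEXUS", "begin trees;", "translate",
             "  1 A,", "  2 B,", "  3 C;",
             sprintf("tree STATE_%d = [&R] %s", seq_len(nTrees) * 1000L,
                     topos[(seq_len(nTrees) - 1L) %% 3L + 1L]),
             "end;")
  writeLines(lines, path)
  path
}

# An ESSReport with fixed topological ESS values (for bound tests).
fixedEssReport <- function(n, pseudo, approx) {
  new("ESSReport", n = as.integer(n), pseudo = pseudo, approx = approx,
      pseudoReplicates = pseudo, threshold = 200, seed = 1L)
}
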