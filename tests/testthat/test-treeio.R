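test_that("parseNewick builds the documented structures", {
  tr <- ptree("((A:1.0,B:1.0):1.0,C:2.0);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)
  kids <- which(tr$edge[, 1] == ape::Ntip(tr) + 1)
  expect_length(kids, 2)  # root has two children

  star <- ptree("(A,B,C);")
  expect_equal(star$Nnode, 1)
  expect_null(star$edge.length)  # absent lengths are missing, not zero

  single <- ptree("A;")
  expect_equal(single$tip.label, "A")
})

test_that("parse errors name the offending character position", {
  expect_error(parseNewick("((A,B),C;"), "character 9")
  expect_error(parseNewick("((A,B),(C,D);"), "character 13")
  expect_error(parseNewick("((A,B),A);"), "duplicate leaf labels: A")
  expect_error(parseNewick(""), "empty")
  expect_error(parseNewick("((A,B),C)"), "';'")
})

test_that("labels keep underscores verbatim and quotes unescape", {
  tr <- ptree("((GY018_borb:1,BB013:1):1,'S. ruficorne':2);")
  expect_true("GY018_borb" %in% tr$tip.label)
  expect_true("S. ruficorne" %in% tr$tip.label)
})

test_that("[&...] comments parse without effect unless retained", {
  plain <- ptree("((A:1,B:1):1,C:2);")
  commented <- ptree("((A[&x=1]:1,B:1)[&rate=0.01]:1,C:2);")
  expect_equal(writeNewick(commented), writeNewick(plain))
  kept <- parseNewick("((A:1,B:1)[&rate=0.01]:1,C:2);",
                      keepAnnotations = TRUE)
  ann <- attr(kept, "annotations")
  expect_true(any(grepl("rate=0.01", ann)))
})

test_that("write/parse round-trips are the identity on canonical form", {
  for (seed in 1:5) {
    tr <- randomTree(6, seed)
    back <- parseNewick(writeNewick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
    # canonical form is a fixed point
    expect_identical(writeNewick(back), writeNewick(tr))
  }
})

test_that("canonical writer orders children by smallest leaf label", {
  a <- writeNewick(ptree("(B:1,A:1);"))
  b <- writeNewick(ptree("(A:1,B:1);"))
  expect_identical(a, b)
  expect_identical(a, "(A:1,B:1);")
  rot1 <- ptree("((C:1,B:1):1,A:2);")
  rot2 <- ptree("(A:2,(B:1,C:1):1);")
  expect_identical(writeNewick(rot1), writeNewick(rot2))
})

test_that("readNexusTrees honours translate tables and burn-in", {
  path <- writeToyNexus(10)
  trace <- readNexusTrees(path, burnin = 0.10)
  expect_s4_class(trace, "TreeTrace")
  expect_length(trace, 9)   # floor(0.1 * 10) = 1 discarded
  expect_equal(traceTaxa(trace), c("A", "B", "C"))
  full <- readNexusTrees(path, burnin = 0)
  expect_length(full, 10)
  # discarded + kept = input count
  expect_equal(length(trace) + 1, length(full))
  # the discarded tree is the leading one
  expect_equal(trace@sampleIndex[1], full@sampleIndex[2])
})

test_that("readNexusTrees agrees with the ape reader on topology", {
  path <- writeToyNexus(6)
  mine <- readNexusTrees(path, burnin = 0)
  oracle <- ape::read.nexus(path)
  for (i in seq_along(oracle)) {
    expect_true(ape::all.equal.phylo(mine@trees[[i]], oracle[[i]],
                                     use.edge.length = FALSE))
  }
})

test_that("readNexusTrees rejects broken files", {
  noTrees <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin taxa;", "end;"), noTrees)
  expect_error(readNexusTrees(noTrees), "no TREES block")

  badMap <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin trees;", "translate", "  1 A,", "  2 B;",
               "tree T1 = ((1,2),3);", "end;"), badMap)
  expect_error(readNexusTrees(badMap, burnin = 0), "no mapping for: 3")

  mixed <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin trees;",
               "tree T1 = ((A,B),C);", "tree T2 = ((A,B),D);", "end;"),
             mixed)
  expect_error(readNexusTrees(mixed, burnin = 0), "different taxon set")
})

test_that("metadata comments in tree statements are topology-neutral", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin trees;",
               "tree T1 = [&R] ((A[&h=1]:1,B:1)[&rate=0.01]:1,C:2);",
               "end;"), f)
  g <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin trees;",
               "tree T1 = ((A:1,B:1):1,C:2);", "end;"), g)
  expect_identical(writeNewick(readNexusTrees(f, burnin = 0)@trees[[1]]),
                   writeNewick(readNexusTrees(g, burnin = 0)@trees[[1]]))
})

test_that("node ages follow the ultrametric definition", {
  ages <- nodeAges(ptree("((A:1,B:1):1,C:2);"))
  expect_equal(unname(ages[c("A", "B", "C")]), c(0, 0, 0))
  expect_equal(unname(ages[5]), 1)   # internal
  expect_equal(unname(ages[4]), 2)   # root
  expect_equal(unname(nodeAges(ptree("A;"))[2]), 0)  # single leaf root
})

test_that("node ages reject non-ultrametric trees, reporting the spread", {
  bad <- ptree("((A:1.0,B:1.1):1.0,C:2.0);")  # depths 2.0 vs 2.1
  expect_error(nodeAges(bad, tolerance = 0.05), "0.1")
  expect_silent(nodeAges(bad, tolerance = 0.15))
  expect_error(nodeAges(ptree("(A,B);")), "missing branch lengths")
})

test_that("node ages are invariant under child reordering", {
  t1 <- ptree("((A:1,B:1):1,C:2);")
  t2 <- ptree("(C:2,(B:1,A:1):1);")
  a1 <- sort(unname(nodeAges(t1)))
  a2 <- sort(unname(nodeAges(t2)))
  expect_equal(a1, a2)
})

test_that("annotated NEXUS output round-trips and embeds comments", {
  tr <- ptree("((A:1,B:1):1,C:2);")
  ann <- character(5); ann[4] <- "median=1.5"
  f <- tempfile(fileext = ".nex")
  writeAnnotatedNexus(tr, f, annotations = ann)
  raw <- paste(readLines(f), collapse = "\n")
  expect_match(raw, "\\[&median=1.5\\]")
  back <- readNexusTrees(f, burnin = 0)
  expect_true(ape::all.equal.phylo(back@trees[[1]], tr,
                                   use.edge.length = TRUE))
})

test_that("a written trace reads back identically", {
  tr <- traceFrom("((A:1,B:1):1,C:2);", "((A:1,C:1):1,B:2);")
  f <- tempfile(fileext = ".nex")
  writeNexusTrace(tr, f)
  back <- readNexusTrees(f, burnin = 0)
  expect_equal(length(back), 2)
  for (i in 1:2)
    expect_identical(writeNewick(back@trees[[i]]),
                     writeNewick(tr@trees[[i]]))
})

test_that("pooling traces is explicit and checks taxon sets", {
  a <- traceFrom("((A,B),C);", "((A,C),B);")
  b <- traceFrom("((B,C),A);")
  pooled <- poolTraces(a, b)
  expect_length(pooled, 3)
  d <- traceFrom("((A,B),D);")
  expect_error(poolTraces(a, d), "different taxon sets")
})
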