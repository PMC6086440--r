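test_that("hpdInterval picks the smallest window, earliest on ties", {
  expect_equal(hpdInterval(1:100, 0.95), c(1, 95))
  expect_equal(hpdInterval(5, 0.95), c(5, 5))
  expect_error(hpdInterval(numeric(0)), "empty")
  # a skewed sample: HPD must hug the dense side
  set.seed(3)
  x <- rexp(20000)
  hpd <- hpdInterval(x, 0.95)
  expect_lt(hpd[1], 0.01)
  expect_lt(hpd[2], quantile(x, 0.975) + 1e-9)
})

test_that("hpdInterval contains the promised mass at minimal width", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(500)
    hpd <- hpdInterval(x, 0.9)
    inside <- sum(x >= hpd[1] & x <= hpd[2])
    expect_gte(inside, ceiling(0.9 * 500))
    ci <- centralInterval(x, 0.9)
    expect_lte(hpd[2] - hpd[1], ci[2] - ci[1] + 1e-9)
  }
})

test_that("mccTree returns the sampled tree with maximal clade score", {
  tr <- traceFrom("((A:1,B:1):1,C:2);", "((A:1,B:1):1,C:2);",
                  "((A:1,C:1):1,B:2);")
  mcc <- mccTree(tr)
  expect_identical(writeNewick(mccPhylo(mcc)),
                   writeNewick(tr@trees[[1]]))
  # exhaustive check: the winner's score is the known maximum
  expect_equal(mcc@score, log(2 / 3))
  # identical-tree trace: supports 1, score 0
  same <- traceFrom("((A:1,B:1):1,C:2);", "((A:1,B:1):1,C:2);")
  m2 <- mccTree(same)
  expect_equal(m2@score, 0)
  expect_true(all(cladeSummaries(m2)$support == 1))
})

test_that("mcc ties go to the earliest sampled tree and are flagged", {
  tr <- traceFrom("((A,B),(C,D));", "((A,C),(B,D));",
                  "((A,B),(C,D));", "((A,C),(B,D));")
  expect_message(mcc <- mccTree(tr), "tie")
  expect_true(mcc@tie)
  expect_identical(writeNewick(mccPhylo(mcc)),
                   writeNewick(tr@trees[[1]]))
})

test_that("mcc recovers the modal topology of a sticky chain", {
  # pi with a 0.6 mode on the first topology
  k <- 105
  pi <- c(0.6, rep(0.4 / (k - 1), k - 1))
  cfg <- stickyChainConfig(LETTERS[1:5], pi = pi, alpha = 0.3,
                           n = 3000L, seed = 9L)
  out <- sampleStickyChain(cfg)
  modal <- enumerateRootedTopologies(LETTERS[1:5])[[1]]
  mcc <- mccTree(out$trace)
  expect_true(ape::all.equal.phylo(mccPhylo(mcc), modal,
                                   use.edge.length = FALSE))
})

test_that("annotateAges summarises ages over clade-containing trees", {
  # trace whose internal clade {A,B} has ages 1..100
  trees <- lapply(1:100, function(a) {
    parseNewick(sprintf("((A:%d,B:%d):%d,C:%d);", a, a, 200 - a, 200))
  })
  tr <- treeTrace(trees)
  mcc <- annotateAges(mccTree(tr), tr, level = 0.95)
  s <- cladeSummaries(mcc)
  ab <- s[s$clade == "A\tB", ]
  expect_equal(ab$median, 50.5)
  expect_equal(c(ab$lower, ab$upper), c(1, 95))
  root <- s[s$clade == "A\tB\tC", ]
  expect_equal(root$median, 200)
  expect_equal(root$upper, root$lower)  # degenerate HPD
})

test_that("age summaries scale linearly with branch lengths", {
  t1 <- traceFrom("((A:1,B:1):1,C:2);", "((A:1.2,B:1.2):0.8,C:2);")
  t2 <- treeTrace(lapply(t1@trees, function(tr) {
    tr$edge.length <- tr$edge.length * 3
    tr
  }))
  s1 <- cladeSummaries(annotateAges(mccTree(t1), t1))
  s2 <- cladeSummaries(annotateAges(mccTree(t2), t2))
  expect_equal(s2$median, 3 * s1$median)
  expect_equal(s2$lower, 3 * s1$lower)
  expect_equal(s2$upper, 3 * s1$upper)
})

test_that("divergenceTable resolves MRCAs and flags non-monophyly", {
  tr <- traceFrom("((A:1,B:1):1,C:2);", "((A:1,B:1):1,C:2);")
  ann <- annotateAges(mccTree(tr), tr)
  div <- divergenceTable(ann, list(
    all = c("A", "B", "C"),    # root
    cherry = c("A", "B"),
    straddle = c("A", "C")))   # not monophyletic: MRCA is the root
  expect_equal(div$median[div$label == "all"], 2)
  expect_equal(div$median[div$label == "cherry"], 1)
  expect_equal(div$median[div$label == "straddle"], 2)
  expect_false(div$monophyletic[div$label == "straddle"])
  expect_true(all(div$monophyletic[div$label != "straddle"]))
  expect_match(formatDivergenceRows(div)[3], "non-monophyletic")
  expect_error(divergenceTable(mccTree(tr), list(a = c("A", "B"))),
               "annotate ages first")
})

test_that("synthetic posterior recovers true node ages within MC error", {
  # i.i.d. lognormal jitter of node ages around a fixed 4-taxon tree
  set.seed(21)
  mk <- function(ab, abc, root) {
    sprintf("(((A:%.10g,B:%.10g):%.10g,C:%.10g):%.10g,D:%.10g);",
            ab, ab, abc - ab, abc, root - abc, root)
  }
  n <- 400
  ab <- rlnorm(n, log(2), 0.1); abc <- ab + rlnorm(n, log(1), 0.1)
  root <- abc + rlnorm(n, log(1.5), 0.1)
  tr <- treeTrace(lapply(seq_len(n), function(i)
    parseNewick(mk(ab[i], abc[i], root[i]))))
  ann <- annotateAges(mccTree(tr), tr)
  div <- divergenceTable(ann, list(ab = c("A", "B")))
  expect_lt(abs(div$median - 2) / 2, 0.05)
  expect_lt(div$lower, 2); expect_gt(div$upper, 2)
})

test_that("MCC output writes annotated NEXUS readable by viewers", {
  tr <- traceFrom("((A:1,B:1):1,C:2);", "((A:1,B:1):1,C:2);",
                  "((A:1,C:1):1,B:2);")
  ann <- annotateAges(mccTree(tr), tr)
  f <- tempfile(fileext = ".nex")
  writeMccNexus(ann, f)
  raw <- paste(readLines(f), collapse = "\n")
  expect_match(raw, "posterior=")
  expect_match(raw, "age_median=")
  expect_match(raw, "age_hpd=\\{")
  back <- ape::read.nexus(f)   # standard readers can open it
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
})
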