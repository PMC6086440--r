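test_that("topology enumeration has the double-factorial counts", {
  expect_length(enumerateRootedTopologies(LETTERS[1:2]), 1)
  expect_length(enumerateRootedTopologies(LETTERS[1:3]), 3)
  expect_length(enumerateRootedTopologies(LETTERS[1:4]), 15)
  expect_length(enumerateRootedTopologies(LETTERS[1:5]), 105)
  expect_error(enumerateRootedTopologies(LETTERS[1:7]), "capped")
  # all topologies are distinct
  keys <- vapply(enumerateRootedTopologies(LETTERS[1:4]), writeNewick, "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("enumeration agrees with the phangorn topology catalogue", {
  skip_if_not_installed("phangorn")
  mine <- enumerateRootedTopologies(LETTERS[1:4])
  oracle <- phangorn::allTrees(4, rooted = TRUE,
                               tip.label = LETTERS[1:4])
  expect_setequal(vapply(mine, writeNewick, ""),
                  vapply(oracle, function(t) {
                    t$edge.length <- NULL
                    writeNewick(t)
                  }, ""))
})

test_that("the cherry-count oracle on 4 taxa is 3/15", {
  # there are exactly 3 rooted topologies on {A,B,C,D} containing the
  # clade {A,B}: one per rooted topology of {AB, C, D}
  topos <- enumerateRootedTopologies(LETTERS[1:4])
  nAB <- sum(vapply(topos, isMonophyletic, TRUE, taxa = c("A", "B")))
  expect_equal(nAB, 3L)
  cfg <- stickyChainConfig(LETTERS[1:4], pi = rep(1 / 15, 15),
                           alpha = 0, n = 10L, seed = 1L)
  truth <- sampleStickyChain(cfg)$truth
  expect_equal(trueCladeProbability(truth, c("A", "B")), 3 / 15)
})

test_that("sticky chains are stationary with the promised mixing law", {
  # alpha = 0: i.i.d. draws, frequencies within 3 multinomial SEs
  k <- 15
  cfg <- stickyChainConfig(LETTERS[1:4], pi = rep(1 / k, k), alpha = 0,
                           n = 20000L, seed = 44L)
  out <- sampleStickyChain(cfg)
  freq <- tabulate(out$truth@topologyIds, k) / 20000
  se <- sqrt((1 / k) * (1 - 1 / k) / 20000)
  expect_true(all(abs(freq - 1 / k) <= 3 * se + 1e-9))
  expect_equal(out$truth@act, 1)

  # alpha = 0.8: indicator autocorrelation ~ alpha^k at small lags
  cfg2 <- stickyChainConfig(LETTERS[1:4], pi = rep(1 / k, k),
                            alpha = 0.8, n = 20000L, seed = 45L)
  out2 <- sampleStickyChain(cfg2)
  expect_equal(out2$truth@act, 9)
  ind <- as.numeric(out2$truth@topologyIds == 1L)
  rho <- as.numeric(acf(ind, lag.max = 5, plot = FALSE)$acf)[-1]
  for (lag in c(1L, 2L, 5L))
    expect_lt(abs(rho[lag] - 0.8^lag), 0.1)
})

test_that("sticky chains are reproducible and validated", {
  cfg <- stickyChainConfig(LETTERS[1:5], alpha = 0.5, n = 100L,
                           seed = 7L)
  a <- sampleStickyChain(cfg)
  b <- sampleStickyChain(cfg)
  expect_identical(a$truth@topologyIds, b$truth@topologyIds)
  expect_equal(sum(a$truth@pi), 1)
  expect_error(validObject(
    stickyChainConfig(LETTERS[1:5], pi = c(0.5, 0.6), alpha = 0.5)),
    "sum to 1")
  expect_error(stickyChainConfig(LETTERS[1:5], alpha = 1), "alpha")
})

test_that("birth-death trees are ultrametric with n extant tips", {
  for (seed in 1:4) {
    cfg <- seqSimConfig(nTaxa = 6, birthRate = 1,
                        relativeDeathRate = 0.3, seed = seed)
    tr <- simulateBDTree(cfg)
    expect_equal(ape::Ntip(tr), 6)
    ages <- nodeAges(tr)   # errors if not ultrametric
    expect_true(all(ages[tr$tip.label] == 0))
    expect_gt(max(ages), 0)
  }
  # pure birth: no pruning, exactly n - 1 internal nodes
  pb <- simulateBDTree(seqSimConfig(nTaxa = 5, birthRate = 1,
                                    relativeDeathRate = 0, seed = 2))
  expect_equal(pb$Nnode, 4)
  # seeded runs are bit-reproducible
  t1 <- simulateBDTree(seqSimConfig(nTaxa = 5, birthRate = 1, seed = 9))
  t2 <- simulateBDTree(seqSimConfig(nTaxa = 5, birthRate = 1, seed = 9))
  expect_identical(writeNewick(t1), writeNewick(t2))
})

test_that("relaxed clock rates honour the lognormal parameterisation", {
  tr <- simulateBDTree(seqSimConfig(nTaxa = 4, birthRate = 1, seed = 1))
  # strict clock at ucldStdev = 0
  expect_equal(assignRelaxedRates(tr, 0.0115, 0, seed = 1),
               rep(0.0115, nrow(tr$edge)))
  # real-scale mean pinned to ucldMean
  big <- ape::rtree(50001)
  r <- assignRelaxedRates(big, 0.0115, 0.5, seed = 3)
  expect_lt(abs(mean(r) - 0.0115) / 0.0115, 0.01)
  cv <- sd(r) / mean(r)
  expect_lt(abs(cv - sqrt(exp(0.5^2) - 1)), 0.02)
})

test_that("discrete gamma categories have mean one and match phangorn", {
  for (shape in c(0.5, 11.1)) {
    g <- discreteGammaRates(shape, 6)
    expect_equal(mean(g), 1, tolerance = 1e-6)
    expect_true(all(diff(g) > 0))
  }
  skip_if_not_installed("phangorn")
  expect_equal(discreteGammaRates(11.1, 6),
               as.numeric(phangorn::discrete.gamma(11.1, 6)),
               tolerance = 1e-6)
})

test_that("alignment simulation respects invariant sites and length", {
  cfg <- seqSimConfig(nTaxa = 2, length = 300, pInv = 1, seed = 6)
  tr <- ptree("(A:5,B:5);")
  aln <- simulateAlignment(tr, 1, cfg)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  expect_equal(ncol(m), 300)
  expect_true(all(m[1, ] == m[2, ]))   # p_inv = 1: constant columns
  # seeded determinism
  a2 <- simulateAlignment(tr, 1, cfg)
  expect_identical(as.character(aln), as.character(a2))
})

test_that("JC simulation recovers the true distance (closed form)", {
  # JC special case: equal frequencies/exchangeabilities, no gamma/inv
  cfg <- seqSimConfig(nTaxa = 2, length = 50000, gammaCategories = 1L,
                      pInv = 0, seed = 8)
  tr <- ptree("(A:0.05,B:0.05);")
  aln <- simulateAlignment(tr, 1, cfg)
  d <- as.numeric(ape::dist.dna(
    ape::as.DNAbin(Biostrings::DNAMultipleAlignment(aln)),
    model = "JC69"))
  truth <- 0.1
  p <- 3 / 4 * (1 - exp(-4 * truth / 3))
  seD <- sqrt(p * (1 - p) / 50000) / (1 - 4 * p / 3)
  expect_lt(abs(d - truth), 3 * seD)
})

test_that("long branches drive base composition to equilibrium", {
  cfg <- seqSimConfig(nTaxa = 2, length = 20000, gammaCategories = 1L,
                      baseFreq = c(0.4, 0.3, 0.2, 0.1), seed = 12)
  tr <- ptree("(A:50,B:50);")
  aln <- simulateAlignment(tr, 1, cfg)
  comp <- colSums(Biostrings::alphabetFrequency(aln)[, c("A", "C", "G",
                                                         "T")])
  comp <- comp / sum(comp)
  se <- sqrt(cfg@baseFreq * (1 - cfg@baseFreq) / (2 * 20000))
  expect_true(all(abs(comp - cfg@baseFreq) <= 3 * se + 0.01))
})

test_that("prior-predictive draws follow the stated priors", {
  expect_equal(sampleModelPriors(1)@ucldMean, 0.0115)
  expect_equal(sampleModelPriors(1, mode = "nuclear")@ucldMean, 0.004)
  draws <- lapply(1:2000, sampleModelPriors)
  pinv <- vapply(draws, function(d) d@pInv, 0)
  rdr <- vapply(draws, function(d) d@relativeDeathRate, 0)
  expect_lt(abs(mean(pinv) - 0.5), 3 * sqrt(1 / 12 / 2000))
  expect_lt(abs(mean(rdr) - 1 / 3),
            3 * sqrt(1 / 18 / 2000))  # Beta(1,2): var = 1/18
  cfg <- draws[[5]]
  expect_equal(cfg@gammaShape, 11.1)
  expect_equal(cfg@gammaCategories, 6L)
  expect_equal(sum(cfg@baseFreq), 1)
})

test_that("simulation truth sidecars serialize the analytic ACT", {
  cfg <- stickyChainConfig(LETTERS[1:4], alpha = 0.5, n = 50L, seed = 2L)
  truth <- sampleStickyChain(cfg)$truth
  f <- tempfile(fileext = ".json")
  writeSimTruth(truth, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$act, 3)   # (1 + 0.5) / (1 - 0.5)
  expect_equal(length(js$pi), 15)
})
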