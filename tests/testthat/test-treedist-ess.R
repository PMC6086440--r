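test_that("pathDistance reproduces the hand-enumerated 4-taxon case", {
  t1 <- ptree("((A,B),(C,D));")
  t2 <- ptree("((A,C),(B,D));")
  # rooted edge-path counts: within-cherry pairs 2, cross pairs 4;
  # swapping B and C flips four pairs by 2 each: sqrt(16) = 4
  expect_equal(pathDistance(t1, t2), 4.0)
  expect_equal(pathDistance(t1, t1), 0)
  expect_error(pathDistance(t1, ptree("((A,B),(C,E));")), "D, E")
})

test_that("pathDistance is a metric on topologies", {
  trees <- lapply(1:6, function(s) randomTree(6, s))
  for (i in seq_along(trees)) {
    expect_equal(pathDistance(trees[[i]], trees[[i]]), 0)
    for (j in seq_along(trees)) {
      dij <- pathDistance(trees[[i]], trees[[j]])
      expect_equal(dij, pathDistance(trees[[j]], trees[[i]]))  # symmetry
      for (k in seq_along(trees)) {
        expect_lte(dij,
                   pathDistance(trees[[i]], trees[[k]]) +
                     pathDistance(trees[[k]], trees[[j]]) + 1e-12)
      }
    }
  }
})

test_that("pathDistance ignores branch lengths", {
  a <- ptree("((A:1,B:2):3,C:4);")
  b <- ptree("((A:9,B:9):9,C:9);")
  expect_equal(pathDistance(a, b), 0)
})

test_that("unrooted path counts agree with the phangorn oracle", {
  skip_if_not_installed("phangorn")
  for (seed in 1:6) {
    t1 <- randomTree(6, seed)
    t2 <- randomTree(6, seed + 100)
    expect_equal(pathDistance(t1, t2, unrooted = TRUE),
                 as.numeric(phangorn::path.dist(t1, t2)))
  }
})

test_that("scalarESS recovers independence and AR(1) autocorrelation", {
  set.seed(42)
  iid <- rnorm(10000)
  expect_gt(scalarESS(iid) / 10000, 0.9)
  expect_lt(scalarESS(iid) / 10000, 1.1)
  # AR(1) with phi = 0.5 has ACT = (1+phi)/(1-phi) = 3
  phi <- 0.5
  x <- as.numeric(stats::arima.sim(list(ar = phi), n = 10000))
  ess <- scalarESS(x)
  expect_gt(ess, 10000 / 3 * 0.85)
  expect_lt(ess, 10000 / 3 * 1.15)
})

test_that("scalarESS rejects degenerate series and stays in [1, N]", {
  expect_error(scalarESS(rep(1, 100)), "zero-variance")
  expect_error(scalarESS(1:5), "too short")
  set.seed(7)
  for (i in 1:5) {
    x <- cumsum(rnorm(200))   # heavily autocorrelated random walk
    e <- scalarESS(x)
    expect_gte(e, 1); expect_lte(e, 200)
  }
})

test_that("pseudo topological ESS is reproducible and guarded", {
  cfg <- stickyChainConfig(LETTERS[1:5], alpha = 0.5, n = 2000L,
                           seed = 5L)
  trace <- sampleStickyChain(cfg)$trace
  a <- pseudoTopoESS(trace, nFocal = 1L, seed = 99L)
  b <- pseudoTopoESS(trace, nFocal = 1L, seed = 99L)
  expect_identical(a$replicates, b$replicates)   # seeded determinism
  expect_equal(a$median, a$replicates)           # single replicate
  one <- traceFrom("((A,B),C);", "((A,B),C);")
  expect_error(pseudoTopoESS(one), "single distinct topology")
})

test_that("pseudo ESS recovers the sticky-chain autocorrelation time", {
  cfg <- stickyChainConfig(LETTERS[1:5], alpha = 0.5, n = 10000L,
                           seed = 31L)
  trace <- sampleStickyChain(cfg)$trace
  ps <- pseudoTopoESS(trace, nFocal = 10L, seed = 8L)
  target <- 10000 * (1 - 0.5) / (1 + 0.5)
  expect_lt(abs(ps$median - target) / target, 0.25)
})

test_that("approximate ESS follows its truncation and lag rules", {
  cfg <- stickyChainConfig(LETTERS[1:5], alpha = 0.5, n = 3000L,
                           seed = 13L)
  trace <- sampleStickyChain(cfg)$trace
  expect_equal(approxTopoESS(trace, maxLag = 0), 3000)  # no lags: ESS = N
  e <- approxTopoESS(trace, seed = 4L)
  expect_gte(e, 1); expect_lte(e, 3000)
  one <- traceFrom("((A,B),C);", "((A,B),C);")
  expect_error(approxTopoESS(one), "single distinct topology")
})

test_that("iid topology draws give near-N topological ESS", {
  cfg <- stickyChainConfig(LETTERS[1:5], alpha = 0, n = 5000L,
                           seed = 77L)
  trace <- sampleStickyChain(cfg)$trace
  ps <- pseudoTopoESS(trace, nFocal = 10L, seed = 3L)
  expect_gt(ps$median / 5000, 0.8)
  expect_lt(ps$median / 5000, 1.2)
  ap <- approxTopoESS(trace, seed = 3L)
  expect_gt(ap / 5000, 0.8)
  expect_lte(ap / 5000, 1.0)   # clamped to [1, N]
})

test_that("essReport assembles scalar and topological entries; gate works", {
  cfg <- stickyChainConfig(LETTERS[1:4], alpha = 0.2, n = 1200L,
                           seed = 15L)
  trace <- sampleStickyChain(cfg)$trace
  set.seed(1)
  rep <- essReport(trace, scalarTraces = list(lik = rnorm(1200)),
                   config = pipelineConfig(seed = 6L))
  expect_s4_class(rep, "ESSReport")
  expect_equal(rep@n, 1200L)
  expect_equal(rep@pseudo, median(rep@pseudoReplicates))
  g <- essGate(rep, threshold = 200)
  expect_true(all(c("lik", "topological (P)", "topological (A)")
                  %in% g$entry))
  expect_true(attr(essGate(rep, threshold = 0), "overall"))
  gFail <- essGate(rep, threshold = 1e6)
  expect_false(attr(gFail, "overall"))
  expect_false(any(gFail$pass))
})

test_that("trace logs round-trip through readTraceLog", {
  f <- tempfile(fileext = ".log")
  writeLines(c("# sampler log", "state\tposterior\tucldMean",
               paste(seq(0, 9000, by = 1000),
                     round(rnorm(10), 4), round(runif(10), 4),
                     sep = "\t")), f)
  df <- readTraceLog(f)
  expect_equal(nrow(df), 10)
  expect_named(df, c("state", "posterior", "ucldMean"))
  df2 <- readTraceLog(f, burnin = 0.10)
  expect_equal(nrow(df2), 9)
})

test_that("ESS reports serialize to JSON with the gate verdict", {
  rep <- fixedEssReport(1000, 400, 500)
  js <- jsonlite::fromJSON(essReportToJson(rep))
  expect_equal(js$n, 1000)
  expect_equal(js$pseudo$median, 400)
  expect_equal(js$approx, 500)
  expect_true(js$gate)
})
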