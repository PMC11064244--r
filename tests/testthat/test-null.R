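test_that("degenerate draws saturate: universe equals formula space", {
  genes <- sprintf("G%02d", 1:20)
  uni <- geneUniverse(genes, "toy")
  fs <- mkSpace(genes, "F1", "formula")
  nd <- sampleNull(fs, uni, k = 20, nDraws = 50, seed = 1)
  expect_true(all(nullSupports(nd) == 1))
  expect_equal(nullMean(nd), 1)
  expect_equal(nullVariance(nd), 0)
})

test_that("a formula disjoint from the universe gives all-zero supports", {
  uni <- geneUniverse(sprintf("G%02d", 1:20), "toy")
  fs <- mkSpace(c("X1", "X2"), "F1", "formula")
  nd <- sampleNull(fs, uni, k = 5, nDraws = 50, seed = 1)
  expect_true(all(nullSupports(nd) == 0))
})

test_that("draw-size and universe-size preconditions are enforced", {
  uni <- geneUniverse(sprintf("G%02d", 1:10), "toy")
  fs <- mkSpace("G01", "F1", "formula")
  expect_error(sampleNull(fs, uni, k = 11, nDraws = 10), "exceeds")
  expect_error(sampleNull(fs, uni, k = 0, nDraws = 10), ">= 1")
  expect_error(hypergeometricMoments(0, 0, 1), "N must")
  expect_error(hypergeometricMoments(10, 2, 0), "k must")
})

test_that("identical seeds give identical draws; the global RNG is untouched", {
  uni <- geneUniverse(sprintf("G%03d", 1:100), "toy")
  fs <- mkSpace(sprintf("G%03d", 1:30), "F1", "formula")
  a <- sampleNull(fs, uni, k = 10, nDraws = 200, seed = 77)
  set.seed(123); probe1 <- runif(1)
  set.seed(123)
  b <- sampleNull(fs, uni, k = 10, nDraws = 200, seed = 77)
  probe2 <- runif(1)
  expect_identical(nullSupports(a), nullSupports(b))
  expect_identical(probe1, probe2)  # RNG state restored around the draws
  c2 <- sampleNull(fs, uni, k = 10, nDraws = 200, seed = 78)
  expect_false(identical(nullSupports(a), nullSupports(c2)))
})

test_that("hypergeometric moments match exhaustive enumeration of all draws", {
  expect_equal(hypergeometricMoments(10, 0, 5),
               list(expectedSupport = 0, supportVariance = 0))
  expect_equal(hypergeometricMoments(10, 10, 5),
               list(expectedSupport = 1, supportVariance = 0))

  # N=4, m=2, k=2: enumerate all C(4,2)=6 draws directly
  draws <- combn(4, 2)
  supports <- apply(draws, 2, function(d) sum(d %in% c(1, 2)) / 2)
  mom <- hypergeometricMoments(4, 2, 2)
  expect_equal(mom$expectedSupport, mean(supports))
  expect_equal(mom$supportVariance, mean((supports - mean(supports))^2))
  expect_equal(mom$supportVariance, 1 / 12)

  # a second, asymmetric case: N=6, m=2, k=3
  draws <- combn(6, 3)
  supports <- apply(draws, 2, function(d) sum(d %in% c(1, 2)) / 3)
  mom <- hypergeometricMoments(6, 2, 3)
  expect_equal(mom$expectedSupport, mean(supports))
  expect_equal(mom$supportVariance, mean((supports - mean(supports))^2))
})

test_that("empirical mean tracks m/N within 3 standard errors across seeds", {
  N <- 600; k <- 40; m <- 90; nDraws <- 400
  uni <- geneUniverse(sprintf("G%03d", 1:N), "toy")
  fs <- mkSpace(sprintf("G%03d", 1:m), "F1", "formula")
  mom <- hypergeometricMoments(N, m, k)
  se <- sqrt(mom$supportVariance / nDraws)
  hits <- vapply(1:20, function(s) {
    nd <- sampleNull(fs, uni, k = k, nDraws = nDraws, seed = s)
    abs(nullMean(nd) - mom$expectedSupport) <= 3 * se
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("empirical p uses the add-one upper tail", {
  uni <- geneUniverse(sprintf("G%03d", 1:100), "toy")
  fs <- mkSpace(sprintf("G%03d", 1:40), "F1", "formula")
  nd <- sampleNull(fs, uni, k = 10, nDraws = 100, seed = 5)
  expect_equal(empiricalP(1, nd), 1 / 101)  # above every draw
  expect_equal(empiricalP(0, nd), 1)        # all draws >= 0
  med <- median(nullSupports(nd))
  # direct-counting oracle on the stored draw list
  expect_equal(empiricalP(med, nd),
               (1 + sum(nullSupports(nd) >= med)) / 101)
  expect_gt(empiricalP(med, nd), 0.3)
  expect_lt(empiricalP(med, nd), 0.8)
  expect_error(empiricalP(1.5, nd), "\\[0, 1\\]")
})

test_that("an observed support passed to sampleNull populates empiricalP", {
  uni <- geneUniverse(sprintf("G%03d", 1:100), "toy")
  fs <- mkSpace(sprintf("G%03d", 1:40), "F1", "formula")
  nd <- sampleNull(fs, uni, k = 10, nDraws = 100, seed = 5, observed = 0.9)
  expect_equal(nd@empiricalP, empiricalP(0.9, nd))
  nd0 <- sampleNull(fs, uni, k = 10, nDraws = 100, seed = 5)
  expect_true(is.na(nd0@empiricalP))
})
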