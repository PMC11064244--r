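# independent oracle: double loop over memberships, no set functions
bruteForceSupport <- function(x, y) {
  hits <- 0L
  for (g in x) {
    found <- FALSE
    for (h in y) if (identical(g, h)) found <- TRUE
    if (found) hits <- hits + 1L
  }
  hits / length(x)
}

test_that("support is the covered fraction of the drug space", {
  x <- mkSpace(c("A", "B", "C", "D"), "mod")
  y <- mkSpace(c("A", "B"), "form", "formula")
  sr <- support(x, y)
  expect_equal(supportValue(sr), 0.5)
  expect_equal(overlapGenes(sr), c("A", "B"))

  expect_equal(supportValue(support(x, x)), 1)
  expect_equal(supportValue(support(x, mkSpace(c("Z1", "Z2"), "f", "formula"))), 0)
})

test_that("empty drug space is an error, empty formula space is support 0", {
  empty <- mkSpace(character(), "mod")
  y <- mkSpace("A", "f", "formula")
  expect_error(support(empty, y), "empty")
  expect_equal(supportValue(support(mkSpace(c("A", "B")), empty)), 0)
})

test_that("support matches brute-force membership counting on a small battery", {
  universe <- sprintf("G%02d", 1:24)
  set.seed(2024)
  for (nx in 1:12) for (ny in 0:12) {
    x <- sample(universe, nx)
    y <- if (ny > 0) sample(universe, ny) else character()
    sr <- support(mkSpace(x), mkSpace(y, "f", "formula"))
    expect_identical(supportValue(sr), bruteForceSupport(sort(unique(x)),
                                                         sort(unique(y))))
    expect_true(all(overlapGenes(sr) %in% x) && all(overlapGenes(sr) %in% y))
  }
})

test_that("adding an overlap gene strictly increases support with X fixed", {
  x <- mkSpace(sprintf("G%d", 1:10))
  y1 <- mkSpace(c("G1", "G2"), "f", "formula")
  y2 <- mkSpace(c("G1", "G2", "G3"), "f", "formula")
  expect_true(supportValue(support(x, y2)) > supportValue(support(x, y1)))
})

test_that("weighted average weights main at 50% and splits the rest equally", {
  sc <- weightedAverage(0.63, c(0.44, 0.66, 0.5, 0.69))
  expect_equal(scoreWeights(sc), c(0.5, 0.125, 0.125, 0.125, 0.125))
  expect_equal(round(weightedAvg(sc), 2), 0.60)

  sc2 <- weightedAverage(0.84, c(0.44, 0.43, 0.70, 0.72, 0.69, 0.62))
  expect_equal(round(weightedAvg(sc2), 2), 0.72)

  # no side modules: score is the main support
  expect_equal(weightedAvg(weightedAverage(0.37)), 0.37)
})

test_that("weighted average is convex and permutation invariant", {
  set.seed(99)
  for (i in 1:20) {
    m <- sample(1:6, 1)
    main <- runif(1)
    sides <- runif(m)
    sc <- weightedAverage(main, sides)
    expect_gte(weightedAvg(sc), min(c(main, sides)) - 1e-12)
    expect_lte(weightedAvg(sc), max(c(main, sides)) + 1e-12)
    perm <- sample(m)
    expect_equal(weightedAvg(weightedAverage(main, sides[perm])),
                 weightedAvg(sc))
    # equal supports are a fixed point
    s <- runif(1)
    expect_equal(weightedAvg(weightedAverage(s, rep(s, m))), s)
  }
})

test_that("weighted average reduces to the mean when mainWeight = 1/(m+1)", {
  sides <- c(0.2, 0.8, 0.5)
  sc <- weightedAverage(0.4, sides, mainWeight = 1 / 4)
  expect_equal(weightedAvg(sc), mean(c(0.4, sides)))
})

test_that("out-of-range supports are rejected", {
  expect_error(weightedAverage(1.2, c(0.5)), "\\[0, 1\\]")
  expect_error(weightedAverage(0.5, c(-0.1)), "\\[0, 1\\]")
  expect_error(weightedAverage(0.5, 0.5, mainWeight = 2), "mainWeight")
})

test_that("compareFormulaToModules assembles supports in module order", {
  modA <- list(def = new("ModuleDefinition", moduleId = "M1",
                         diseaseLabel = "Main", role = "main",
                         drugIds = "d1"),
               space = mkSpace(c("A", "B", "C", "D"), "M1"))
  modB <- list(def = new("ModuleDefinition", moduleId = "M2",
                         diseaseLabel = "Side", role = "side_effect",
                         drugIds = "d2"),
               space = mkSpace(c("A", "E"), "M2"))
  fs <- mkSpace(c("A", "B"), "F1", "formula")
  res <- compareFormulaToModules(fs, list(modA, modB))
  expect_equal(supportValue(res$supports[[1]]), 0.5)
  expect_equal(supportValue(res$supports[[2]]), 0.5)
  expect_equal(weightedAvg(res$score), 0.5)
  expect_equal(res$score@mainModuleId, "M1")
  expect_equal(res$score@sideModuleIds, "M2")

  # single main module only
  solo <- compareFormulaToModules(fs, list(modA))
  expect_equal(weightedAvg(solo$score), 0.5)

  # zero or two main modules is a configuration error
  expect_error(compareFormulaToModules(fs, list(modB)), "exactly one")
  expect_error(compareFormulaToModules(fs, list(modA, modA)), "exactly one")
})
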