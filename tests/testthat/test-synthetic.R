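test_that("generated universes are deterministic and sized exactly", {
  u <- generateUniverse(3000, seed = 4)
  expect_length(genes(u), 3000L)
  expect_identical(genes(u), genes(generateUniverse(3000, seed = 4)))
  expect_length(genes(generateUniverse(1)), 1L)
  withCyp <- generateUniverse(200, seed = 1, cypFraction = 0.1)
  expect_equal(sum(isCyp(genes(withCyp))), 20L)
  # the seed places the CYP-styled names
  expect_identical(genes(withCyp),
                   genes(generateUniverse(200, seed = 1, cypFraction = 0.1)))
  expect_false(identical(genes(withCyp),
                         genes(generateUniverse(200, seed = 2,
                                                cypFraction = 0.1))))
})

test_that("infeasible configs are rejected", {
  expect_error(smallConfig(plantedOverlaps = c(50, 6)), "plantedOverlaps")
  expect_error(generateDataset(smallConfig(universeSize = 60)), "infeasible")
  expect_error(
    generateDataset(smallConfig(formulaSpaceSize = 50,
                                plantedOverlaps = c(40, 20))),
    "infeasible")
})

test_that("generated bundles pass the IO schema validations", {
  b <- generateDataset(smallConfig(toxicFraction = 0.2, cypFraction = 0.05))
  fh <- loadAssociationTable(b$paths[["formula_herb"]], "formula_herb")
  hc <- loadAssociationTable(b$paths[["herb_compound"]], "herb_compound")
  ct <- loadAssociationTable(b$paths[["compound_target"]], "compound_target")
  dt <- loadAssociationTable(b$paths[["drug_target"]], "drug_target")
  adm <- loadAdmetTable(b$paths[["admet"]])
  mods <- loadModuleDefinitions(b$paths[["modules"]])
  expect_s4_class(fh, "AssociationTable")
  expect_s4_class(adm, "AdmetTable")
  expect_length(mods, 2L)
  expect_equal(moduleRole(mods[[1]]), "main")
  # every compound in the compound-target table is annotated
  expect_true(all(unique(edges(ct)$source) %in%
                  annotations(adm)$compound_id))
})

test_that("the planted formula space is recovered exactly by the builders", {
  cfg <- smallConfig(formulaSpaceSize = 84, moduleSizes = c(90, 40),
                     plantedOverlaps = c(42, 10), universeSize = 500)
  b <- generateDataset(cfg)
  fh <- loadAssociationTable(b$paths[["formula_herb"]], "formula_herb")
  hc <- loadAssociationTable(b$paths[["herb_compound"]], "herb_compound")
  ct <- loadAssociationTable(b$paths[["compound_target"]], "compound_target")
  sp <- buildFormulaSpace("F1", fh, hc, ct, excludeCyp = FALSE)
  expect_length(genes(sp), 84L)
  # oracle: direct union over the generator's planted edges
  e <- edges(ct); he <- edges(hc); fe <- edges(fh)
  myCompounds <- he$target[he$source %in% fe$target[fe$source == "F1"]]
  expect_identical(genes(sp), sort(unique(e$target[e$source %in% myCompounds])))
})

test_that("planted overlaps and module sizes appear verbatim in the truth ledger", {
  b <- generateDataset(smallConfig())
  firstPair <- b$truth$pairs[[1]]
  expect_equal(firstPair$planted_overlap, 20L)
  expect_equal(firstPair$module_size, 40L)
  expect_equal(firstPair$expected_support, 0.5)
  # with no toxicity and no CYPs, every filtered expectation equals the raw one
  for (p in b$truth$pairs) {
    expect_equal(p$expected_support_cyp, p$expected_support)
    expect_equal(p$expected_support_admet, p$expected_support)
    expect_equal(p$expected_support_cyp_admet, p$expected_support)
  }
})

test_that("toxicFraction 1 with single-carrier genes empties the formula space", {
  cfg <- smallConfig(toxicFraction = 1)
  b <- generateDataset(cfg)
  for (p in b$truth$pairs) expect_equal(p$expected_support_admet, 0)
  fh <- loadAssociationTable(b$paths[["formula_herb"]], "formula_herb")
  hc <- loadAssociationTable(b$paths[["herb_compound"]], "herb_compound")
  ct <- loadAssociationTable(b$paths[["compound_target"]], "compound_target")
  adm <- loadAdmetTable(b$paths[["admet"]])
  kept <- applyAdmetFilter(unique(edges(hc)$target), adm, admetRules())$kept
  expect_length(kept, 0L)
  expect_warning(
    sp <- buildFormulaSpace("F1", fh, hc, ct, keptCompounds = kept),
    "empty target space")
  expect_length(genes(sp), 0L)
})

test_that("with cypFraction 0 the CYP switch has no effect end to end", {
  b <- generateDataset(smallConfig(seed = 21))
  on <- runPipeline(runConfigFromBundle(b, nullDraws = 0, excludeCyp = TRUE,
                                        outDir = tempfile()))
  off <- runPipeline(runConfigFromBundle(b, nullDraws = 0, excludeCyp = FALSE,
                                         outDir = tempfile()))
  expect_equal(vapply(on$scores, weightedAvg, 0),
               vapply(off$scores, weightedAvg, 0))
})

test_that("redundant gene-to-compound assignment survives single exclusions", {
  # redundancy 2: one toxic carrier no longer removes a planted gene
  cfg <- smallConfig(redundancy = 2, toxicFraction = 0.3, seed = 13)
  b <- generateDataset(cfg)
  raw <- vapply(b$truth$pairs, function(p) p$expected_support, 0)
  filt <- vapply(b$truth$pairs, function(p) p$expected_support_admet, 0)
  expect_true(all(filt <= raw))
  # with duplication most planted genes keep at least one clean carrier
  expect_gt(mean(filt / raw), 0.7)
})
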