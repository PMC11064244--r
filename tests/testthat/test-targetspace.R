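test_that("symbol normalization is idempotent and preserves distinctness", {
  raw <- c(" alb ", "GABRB1", "gabrb1", "Cyp3a4")
  once <- normalizeGeneSymbols(raw)
  expect_identical(normalizeGeneSymbols(once), once)
  expect_setequal(unique(once), c("ALB", "GABRB1", "CYP3A4"))
  expect_error(normalizeGeneSymbols("   "), "empty")
})

test_that("CYP isozyme rule requires CYP followed by a digit", {
  expect_true(isCyp("CYP3A4"))
  expect_true(isCyp("CYP1A2"))
  expect_true(isCyp("CYP2D6"))
  expect_false(isCyp("UGT1A9"))   # retained in published overlap lists
  expect_false(isCyp("CYPX"))
  expect_false(isCyp("ALB"))
  # regex oracle over an enumerated symbol list
  syms <- c("CYP3A4", "CYP2C19", "CYP11B1", "CYPX", "CYP", "MYCYP1", "ACYP1",
            "UGT1A9", "GABRB1", "CYP051Z")
  oracle <- vapply(syms, function(s)
    substr(s, 1, 3) == "CYP" && substr(s, 4, 4) %in% as.character(0:9), TRUE)
  expect_identical(isCyp(syms), unname(oracle))
})

test_that("formula space is the union over herbs and kept compounds", {
  tabs <- mkFormulaTables(list(c1 = c("ALB", "CYP3A4"), c2 = "TSPO"))
  sp <- buildFormulaSpace("F1", tabs$fh, tabs$hc, tabs$ct, excludeCyp = TRUE)
  expect_equal(genes(sp), c("ALB", "TSPO"))
  expect_true("cyp_excluded" %in% filtersApplied(sp))

  sp2 <- buildFormulaSpace("F1", tabs$fh, tabs$hc, tabs$ct, excludeCyp = FALSE)
  expect_equal(genes(sp2), c("ALB", "CYP3A4", "TSPO"))

  # ADMET-filtered compounds no longer contribute targets
  sp3 <- buildFormulaSpace("F1", tabs$fh, tabs$hc, tabs$ct,
                           keptCompounds = "c2", excludeCyp = TRUE)
  expect_equal(genes(sp3), "TSPO")
  expect_true("admet_filtered" %in% filtersApplied(sp3))
})

test_that("formula with no herbs errors; all-filtered formula only warns", {
  tabs <- mkFormulaTables(list(c1 = "ALB"))
  expect_error(buildFormulaSpace("F9", tabs$fh, tabs$hc, tabs$ct), "no herbs")
  expect_warning(
    sp <- buildFormulaSpace("F1", tabs$fh, tabs$hc, tabs$ct,
                            keptCompounds = character()),
    "empty target space")
  expect_length(genes(sp), 0L)
})

test_that("module space is the deduplicated union of its drugs' targets", {
  dt <- associationTable(c("d1", "d1", "d2", "d2", "d2"),
                         c("A", "B", "B", "C", "B"), "drug_target")
  mod <- new("ModuleDefinition", moduleId = "M1", diseaseLabel = "X",
             role = "main", drugIds = c("d1", "d2"))
  sp <- buildModuleSpace(mod, dt, excludeCyp = FALSE)
  expect_equal(genes(sp), c("A", "B", "C"))

  # drugs outside the module do not leak in
  dt2 <- associationTable(c("d1", "d3"), c("A", "Z"), "drug_target")
  sp2 <- buildModuleSpace(mod, dt2, excludeCyp = FALSE)
  expect_equal(genes(sp2), "A")
})

test_that("association counts can exceed distinct targets in a module space", {
  # 38 drugs, 88 drug-target rows, 84 distinct targets
  drugs <- sprintf("d%02d", 1:38)
  targets <- sprintf("T%03d", 1:84)
  src <- rep_len(drugs, 84)
  extra_src <- drugs[c(38, 37, 36, 35)]
  extra_tgt <- targets[1:4]                 # second drug for 4 targets
  dt <- associationTable(c(src, extra_src), c(targets, extra_tgt),
                         "drug_target")
  expect_equal(nrow(edges(dt)), 88L)
  mod <- new("ModuleDefinition", moduleId = "M1b", diseaseLabel = "Diabetes",
             role = "main", drugIds = drugs)
  sp <- buildModuleSpace(mod, dt, excludeCyp = FALSE)
  expect_length(genes(sp), 84L)
})

test_that("empty module space is an error (support denominator undefined)", {
  dt <- associationTable("d1", "CYP3A4", "drug_target")
  mod <- new("ModuleDefinition", moduleId = "M1", diseaseLabel = "X",
             role = "main", drugIds = "d1")
  expect_error(buildModuleSpace(mod, dt, excludeCyp = TRUE), "empty")
})

test_that("CYP exclusion commutes with the union and is complete", {
  set.seed(5)
  pool <- c(sprintf("G%03d", 1:40), sprintf("CYP%dA1", 1:8))
  split1 <- sample(pool, 25)
  split2 <- sample(pool, 25)
  dt <- associationTable(c(rep("d1", 25), rep("d2", 25)),
                         c(split1, split2), "drug_target")
  mod <- new("ModuleDefinition", moduleId = "M", diseaseLabel = "X",
             role = "main", drugIds = c("d1", "d2"))
  built <- genes(buildModuleSpace(mod, dt, excludeCyp = TRUE))
  # union-then-filter oracle
  oracle <- sort(setdiff(union(split1, split2),
                         grep("^CYP[0-9]", pool, value = TRUE)))
  expect_identical(built, oracle)
  expect_false(any(isCyp(built)))
})

test_that("adding a drug never shrinks a module space", {
  dt <- associationTable(c("d1", "d2", "d3"), c("A", "B", "C"), "drug_target")
  m1 <- new("ModuleDefinition", moduleId = "M", diseaseLabel = "X",
            role = "main", drugIds = "d1")
  m2 <- new("ModuleDefinition", moduleId = "M", diseaseLabel = "X",
            role = "main", drugIds = c("d1", "d2"))
  expect_true(all(genes(buildModuleSpace(m1, dt, FALSE)) %in%
                  genes(buildModuleSpace(m2, dt, FALSE))))
})

test_that("a space tagged cyp_excluded cannot hold CYP symbols", {
  expect_error(
    new("TargetSpace", ownerId = "x", ownerKind = "formula",
        genes = c("ALB", "CYP3A4"), filtersApplied = "cyp_excluded"),
    "CYP")
})
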