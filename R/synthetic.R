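#' Configure the synthetic dataset generator
#'
#' The generator emulates the structure of a curated herbal-medicine study:
#' a gene universe on the scale of a drug-target database (default 3000
#' genes), formulas composed of herbs that each contribute many compounds,
#' and drug modules (first one the main indication, the rest side-effect
#' modules) whose pooled target spaces share an exactly known number of
#' genes with every formula's target space. Defaults mirror the published
#' study conditions: a main module of 84 target genes backed by 38 drugs and
#' 88 drug-target associations, 1000-draw nulls from a 3000-gene universe,
#' formulas of 4-14 herbs with 6-50 compounds per herb.
#'
#' @param universeSize genes in the universe (default 3000)
#' @param nFormulas formulas to generate (default 10)
#' @param herbsPerFormula integer range c(min, max) (default c(4, 14))
#' @param compoundsPerHerb integer range c(min, max) (default c(6, 50))
#' @param formulaSpaceSize genes per formula space (default 120)
#' @param moduleSizes genes per module space, main first (default c(84, 50, 50))
#' @param moduleLabels disease labels for report rows
#' @param plantedOverlaps genes shared between each formula space and each
#'   module space (default c(59, 25, 25), i.e. main support 59/84 ~ 0.70)
#' @param toxicFraction fraction of compounds flagged by an ADMET rule
#'   (default 0.1); flagged compounds rotate through the AMES /
#'   carcinogenicity / hERG triggers
#' @param cypFraction fraction of universe genes with CYP-isozyme-style
#'   names (default 0.05)
#' @param redundancy compounds each formula-space gene is assigned to
#'   (default 1: excluding a compound removes its genes predictably)
#' @param seed integer seed (default 1)
#' @return a validated \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(universeSize = 3000, nFormulas = 10,
                            herbsPerFormula = c(4, 14),
                            compoundsPerHerb = c(6, 50),
                            formulaSpaceSize = 120,
                            moduleSizes = c(84, 50, 50),
                            moduleLabels = NULL,
                            plantedOverlaps = c(59, 25, 25),
                            toxicFraction = 0.1, cypFraction = 0.05,
                            redundancy = 1, seed = 1) {
  if (is.null(moduleLabels))
    moduleLabels <- c("MainIndication",
                      if (length(moduleSizes) > 1)
                        sprintf("SideEffect%d", seq_len(length(moduleSizes) - 1)))
  new("SyntheticConfig",
      universeSize = as.integer(universeSize),
      nFormulas = as.integer(nFormulas),
      herbsPerFormula = as.integer(herbsPerFormula),
      compoundsPerHerb = as.integer(compoundsPerHerb),
      formulaSpaceSize = as.integer(formulaSpaceSize),
      moduleSizes = as.integer(moduleSizes),
      moduleLabels = as.character(moduleLabels),
      plantedOverlaps = as.integer(plantedOverlaps),
      toxicFraction = as.numeric(toxicFraction),
      cypFraction = as.numeric(cypFraction),
      redundancy = as.integer(redundancy),
      seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic gene universe
#'
#' Symbols are G000001, G000002, ...; a configurable fraction is renamed in
#' CYP-isozyme style (CYP001X, ...) at seed-determined positions so the CYP
#' exclusion path is exercised. Deterministic under \code{seed}.
#'
#' @param size number of genes, >= 1
#' @param seed integer seed
#' @param cypFraction fraction of genes given CYP-style names (default 0)
#' @return a \linkS4class{GeneUniverse}
#' @export
generateUniverse <- function(size, seed = 1, cypFraction = 0) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  syms <- sprintf("G%06d", seq_len(size))
  nCyp <- round(cypFraction * size)
  if (nCyp > 0) {
    pos <- .withSeed(seed, sample.int(size, nCyp))
    syms[pos] <- sprintf("CYP%03dX", seq_len(nCyp))
  }
  geneUniverse(syms, sourceTag = sprintf("synthetic(size=%d, seed=%d)", size,
                                         as.integer(seed)))
}

.sampleRange <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

#' Generate a complete synthetic input bundle
#'
#' Writes the six input TSVs consumed by the pipeline (formula_herb,
#' herb_compound, compound_target, drug_target, modules, admet) plus a
#' \code{truth.json} ground-truth ledger into \code{dir}. Module target
#' spaces are mutually disjoint subsets of the universe; each formula space
#' contains exactly \code{plantedOverlaps[i]} genes of module i's space plus
#' filler genes outside every module space, so the raw expected support of
#' formula f against module i is exactly plantedOverlaps[i] / moduleSizes[i].
#'
#' The ledger records, per (formula, module) pair, the planted overlap and
#' the exact expected support under each filter combination (none, CYP
#' exclusion, ADMET filter with the default all-rules-on keep-unknown rule
#' set, and both) computed by direct set algebra over the generated
#' structures, so end-to-end pipeline runs can be checked exactly.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param dir output directory (created if absent)
#' @return invisibly, a list with \code{dir}, named file \code{paths}, and
#'   the \code{truth} ledger
#' @export
generateDataset <- function(config, dir = tempfile("synth")) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  nMod <- length(config@moduleSizes)
  if (sum(config@moduleSizes) > config@universeSize)
    stop("infeasible config: module spaces (disjoint) exceed the universe")
  if (sum(config@plantedOverlaps) > config@formulaSpaceSize)
    stop("infeasible config: planted overlaps exceed formulaSpaceSize")
  nFiller <- config@formulaSpaceSize - sum(config@plantedOverlaps)
  if (config@universeSize - sum(config@moduleSizes) < nFiller)
    stop("infeasible config: not enough non-module genes for formula filler")

  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory: %s", dir))

  out <- .withSeed(config@seed, {
    uni <- generateUniverse(config@universeSize, seed = config@seed,
                            cypFraction = config@cypFraction)
    pool <- sample(uni@genes)  # shuffled universe

    # mutually disjoint module spaces off the front of the shuffled pool
    moduleSpaces <- vector("list", nMod)
    offset <- 0L
    for (i in seq_len(nMod)) {
      moduleSpaces[[i]] <- pool[(offset + 1L):(offset + config@moduleSizes[i])]
      offset <- offset + config@moduleSizes[i]
    }
    fillerPool <- if (offset < length(pool))
      pool[(offset + 1L):length(pool)] else character()

    moduleIds <- sprintf("M%d", seq_len(nMod))
    roles <- c("main", rep("side_effect", nMod - 1L))

    # drug-target table: ~38 drugs per 84 targets, plus ~5% duplicate-target
    # edges so association counts exceed distinct-target counts
    drugSrc <- character(); drugTgt <- character()
    moduleDrugs <- vector("list", nMod)
    for (i in seq_len(nMod)) {
      sz <- config@moduleSizes[i]
      nDrugs <- max(2L, round(sz * 38 / 84))
      drugs <- sprintf("%s_D%02d", moduleIds[i], seq_len(nDrugs))
      moduleDrugs[[i]] <- drugs
      assign_to <- sample(rep_len(drugs, sz))
      drugSrc <- c(drugSrc, assign_to)
      drugTgt <- c(drugTgt, moduleSpaces[[i]])
      nExtra <- max(1L, round(0.05 * sz))
      extraGenes <- sample(moduleSpaces[[i]], nExtra)
      for (g in extraGenes) {
        owner <- assign_to[match(g, moduleSpaces[[i]])]
        other <- sample(setdiff(drugs, owner), 1L)
        drugSrc <- c(drugSrc, other)
        drugTgt <- c(drugTgt, g)
      }
    }

    formulaIds <- sprintf("F%d", seq_len(config@nFormulas))
    fhSrc <- character(); fhTgt <- character()
    hcSrc <- character(); hcTgt <- character()
    ctSrc <- character(); ctTgt <- character()
    allCompounds <- character()
    formulaGenes <- list()        # formula -> its planted space
    compoundGenes <- list()       # compound -> its genes

    for (f in formulaIds) {
      planted <- unlist(lapply(seq_len(nMod), function(i)
        sample(moduleSpaces[[i]], config@plantedOverlaps[i])))
      filler <- if (nFiller > 0) sample(fillerPool, nFiller) else character()
      fGenes <- c(planted, filler)
      formulaGenes[[f]] <- fGenes

      nHerbs <- .sampleRange(config@herbsPerFormula)
      herbs <- sprintf("%s_H%02d", f, seq_len(nHerbs))
      fhSrc <- c(fhSrc, rep(f, nHerbs)); fhTgt <- c(fhTgt, herbs)
      compounds <- character()
      for (h in herbs) {
        nComp <- .sampleRange(config@compoundsPerHerb)
        comp <- sprintf("%s_C%02d", h, seq_len(nComp))
        hcSrc <- c(hcSrc, rep(h, nComp)); hcTgt <- c(hcTgt, comp)
        compounds <- c(compounds, comp)
      }
      if (length(compounds) < config@redundancy)
        stop("infeasible config: fewer compounds than redundancy")
      for (g in fGenes) {
        carriers <- sample(compounds, config@redundancy)
        ctSrc <- c(ctSrc, carriers); ctTgt <- c(ctTgt, rep(g, config@redundancy))
        for (cc in carriers)
          compoundGenes[[cc]] <- c(compoundGenes[[cc]], g)
      }
      allCompounds <- c(allCompounds, compounds)
    }

    # ADMET annotations: an exact fraction of compounds is flagged, rotating
    # through the three rule triggers
    nToxic <- round(config@toxicFraction * length(allCompounds))
    toxic <- if (nToxic > 0) sample(allCompounds, nToxic) else character()
    trigger <- rep_len(c("ames", "carc", "herg"), length(toxic))
    ames <- rep("non-toxic", length(allCompounds))
    carc <- rep("safe", length(allCompounds))
    herg <- rep("non-inhibitor", length(allCompounds))
    names(ames) <- names(carc) <- names(herg) <- allCompounds
    ames[toxic[trigger == "ames"]] <- "toxic"
    carc[toxic[trigger == "carc"]] <- "danger"
    herg[toxic[trigger == "herg"]] <- sample(c("inhibitor", "strong inhibitor"),
                                             sum(trigger == "herg"),
                                             replace = TRUE)

    list(uni = uni, moduleSpaces = moduleSpaces, moduleIds = moduleIds,
         roles = roles, drugSrc = drugSrc, drugTgt = drugTgt,
         fhSrc = fhSrc, fhTgt = fhTgt, hcSrc = hcSrc, hcTgt = hcTgt,
         ctSrc = ctSrc, ctTgt = ctTgt,
         formulaIds = formulaIds, formulaGenes = formulaGenes,
         compoundGenes = compoundGenes, allCompounds = allCompounds,
         toxic = toxic, ames = ames, carc = carc, herg = herg)
  })

  # ---- write the six TSVs --------------------------------------------------
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    p
  }
  paths <- c(
    formula_herb = wtsv(data.frame(formula_id = out$fhSrc, herb_id = out$fhTgt),
                        "formula_herb.tsv"),
    herb_compound = wtsv(data.frame(herb_id = out$hcSrc, compound_id = out$hcTgt),
                         "herb_compound.tsv"),
    compound_target = wtsv(data.frame(compound_id = out$ctSrc,
                                      gene_symbol = out$ctTgt),
                           "compound_target.tsv"),
    drug_target = wtsv(data.frame(drug_id = out$drugSrc, gene_symbol = out$drugTgt),
                       "drug_target.tsv"),
    modules = wtsv({
      nDrugs <- vapply(seq_along(out$moduleIds), function(i)
        sum(startsWith(unique(out$drugSrc), paste0(out$moduleIds[i], "_"))), 0L)
      data.frame(
        module_id = rep(out$moduleIds, nDrugs),
        disease_label = rep(config@moduleLabels, nDrugs),
        role = rep(out$roles, nDrugs),
        drug_id = unlist(lapply(out$moduleIds, function(m)
          sort(unique(out$drugSrc[startsWith(out$drugSrc, paste0(m, "_"))]))))
      )
    }, "modules.tsv"),
    admet = wtsv(data.frame(compound_id = out$allCompounds,
                            ames = unname(out$ames),
                            carcinogenicity = unname(out$carc),
                            herg = unname(out$herg)),
                 "admet.tsv"),
    universe = wtsv(data.frame(gene_symbol = out$uni@genes), "universe.tsv")
  )

  # ---- ground-truth ledger by direct set algebra ---------------------------
  keptCompounds <- setdiff(out$allCompounds, out$toxic)
  carrierMap <- split(out$ctSrc, out$ctTgt)  # gene -> carrier compounds
  pairs <- list()
  for (f in out$formulaIds) {
    fGenes <- out$formulaGenes[[f]]
    # a gene survives the ADMET filter iff at least one of its carrier
    # compounds within this formula is kept
    survives <- vapply(fGenes, function(g) {
      carriers <- carrierMap[[g]]
      carriers <- carriers[startsWith(carriers, paste0(f, "_"))]
      any(carriers %in% keptCompounds)
    }, TRUE)
    fAdmet <- fGenes[survives]
    for (i in seq_along(out$moduleIds)) {
      mGenes <- out$moduleSpaces[[i]]
      mCyp <- mGenes[!isCyp(mGenes)]
      sup <- function(x, y) length(intersect(x, y)) / length(x)
      pairs[[length(pairs) + 1L]] <- list(
        formula_id = f, module_id = out$moduleIds[i],
        module_size = length(mGenes),
        module_size_cyp_excluded = length(mCyp),
        planted_overlap = config@plantedOverlaps[i],
        expected_support = config@plantedOverlaps[i] / length(mGenes),
        expected_support_cyp = if (length(mCyp)) sup(mCyp, fGenes[!isCyp(fGenes)]) else NA,
        expected_support_admet = sup(mGenes, fAdmet),
        expected_support_cyp_admet = if (length(mCyp))
          sup(mCyp, fAdmet[!isCyp(fAdmet)]) else NA
      )
    }
  }
  truth <- list(
    config = list(universe_size = config@universeSize,
                  n_formulas = config@nFormulas,
                  formula_space_size = config@formulaSpaceSize,
                  module_sizes = config@moduleSizes,
                  planted_overlaps = config@plantedOverlaps,
                  toxic_fraction = config@toxicFraction,
                  cyp_fraction = config@cypFraction,
                  redundancy = config@redundancy,
                  seed = config@seed),
    n_compounds = length(out$allCompounds),
    n_toxic_compounds = length(out$toxic),
    pairs = pairs
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, truth = file.path(dir, "truth.json"))

  invisible(list(dir = dir, paths = paths, truth = truth))
}
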