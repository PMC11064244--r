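.makeSpace <- function(ownerId, ownerKind, genes, excludeCyp, extraTags = character()) {
  genes <- sort(unique(genes))
  tags <- extraTags
  if (excludeCyp) {
    genes <- genes[!isCyp(genes)]
    tags <- c(tags, "cyp_excluded")
  }
  new("TargetSpace", ownerId = ownerId, ownerKind = ownerKind,
      genes = genes, filtersApplied = tags)
}

.neighbors <- function(tab, ids) {
  e <- tab@edges
  unique(e$target[e$source %in% ids])
}

#' Build the target space of a herbal formula
#'
#' Walks formula -> herbs -> compounds -> target genes and takes the union of
#' the targets of every kept compound. Compounds excluded by the ADMET filter
#' are passed via \code{keptCompounds}; CYP isozymes are removed when
#' \code{excludeCyp} (the default), since they reflect drug metabolism rather
#' than therapeutic action.
#'
#' A formula with no herbs is an error (it cannot exist in curated data); a
#' formula whose compounds are all filtered out yields an empty space with a
#' warning, so batch runs over many formulas complete.
#'
#' @param formulaId formula identifier
#' @param formulaHerb,herbCompound,compoundTarget the three
#'   \linkS4class{AssociationTable}s of the respective kinds
#' @param keptCompounds compound ids surviving the ADMET filter, or NULL to
#'   use all compounds
#' @param excludeCyp remove CYP isozyme symbols (default TRUE)
#' @return a \linkS4class{TargetSpace} with provenance tags
#' @export
buildFormulaSpace <- function(formulaId, formulaHerb, herbCompound,
                              compoundTarget, keptCompounds = NULL,
                              excludeCyp = TRUE) {
  stopifnot(formulaHerb@kind == "formula_herb",
            herbCompound@kind == "herb_compound",
            compoundTarget@kind == "compound_target")
  herbs <- .neighbors(formulaHerb, formulaId)
  if (length(herbs) == 0L)
    stop(sprintf("formula '%s' has no herbs in the formula-herb table", formulaId))
  compounds <- .neighbors(herbCompound, herbs)
  tags <- character()
  if (!is.null(keptCompounds)) {
    compounds <- intersect(compounds, keptCompounds)
    tags <- "admet_filtered"
  }
  genes <- .neighbors(compoundTarget, compounds)
  if (length(genes) == 0L)
    warning(sprintf("formula '%s' has an empty target space after filtering",
                    formulaId))
  .makeSpace(formulaId, "formula", genes, excludeCyp, tags)
}

#' Build the target space of a single herb
#'
#' Same construction as \code{\link{buildFormulaSpace}} but starting from one
#' herb: the union of the targets of its kept compounds. Used for per-herb
#' overlap analyses (e.g. scoring each herb of a four-herb formula against a
#' drug module separately).
#'
#' @param herbId herb identifier
#' @param herbCompound,compoundTarget \linkS4class{AssociationTable}s
#' @param keptCompounds compound ids surviving the ADMET filter, or NULL
#' @param excludeCyp remove CYP isozyme symbols (default TRUE)
#' @return a \linkS4class{TargetSpace}
#' @export
buildHerbSpace <- function(herbId, herbCompound, compoundTarget,
                           keptCompounds = NULL, excludeCyp = TRUE) {
  stopifnot(herbCompound@kind == "herb_compound",
            compoundTarget@kind == "compound_target")
  compounds <- .neighbors(herbCompound, herbId)
  if (length(compounds) == 0L)
    stop(sprintf("herb '%s' has no compounds in the herb-compound table", herbId))
  tags <- character()
  if (!is.null(keptCompounds)) {
    compounds <- intersect(compounds, keptCompounds)
    tags <- "admet_filtered"
  }
  genes <- .neighbors(compoundTarget, compounds)
  if (length(genes) == 0L)
    warning(sprintf("herb '%s' has an empty target space after filtering", herbId))
  .makeSpace(herbId, "herb", genes, excludeCyp, tags)
}

#' Build the pooled target space of a drug module
#'
#' The union of the targets of every drug in the module, with duplicate edges
#' collapsed. The module space is the denominator of the support statistic,
#' so an empty union is an error rather than a warning. CYP exclusion is
#' applied symmetrically to formula and module spaces so the support
#' denominator stays consistent.
#'
#' @param module a \linkS4class{ModuleDefinition}
#' @param drugTarget a drug-target \linkS4class{AssociationTable}
#' @param excludeCyp remove CYP isozyme symbols (default TRUE)
#' @return a \linkS4class{TargetSpace} with \code{ownerKind = "drug_module"}
#' @export
buildModuleSpace <- function(module, drugTarget, excludeCyp = TRUE) {
  stopifnot(is(module, "ModuleDefinition"), drugTarget@kind == "drug_target")
  genes <- .neighbors(drugTarget, module@drugIds)
  space <- .makeSpace(module@moduleId, "drug_module", genes, excludeCyp)
  if (length(space@genes) == 0L)
    stop(sprintf("drug module '%s' has an empty target space (support undefined)",
                 module@moduleId))
  space
}
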