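#' @import methods
NULL

## Closed vocabularies shared by the IO layer and the ADMET filter.
.assocKinds <- c("formula_herb", "herb_compound", "compound_target", "drug_target")
.amesLevels <- c("toxic", "non-toxic", "unknown")
.carcLevels <- c("danger", "safe", "unknown")
.hergLevels <- c("strong inhibitor", "inhibitor", "non-inhibitor", "unknown")
.moduleRoles <- c("main", "side_effect")

#' AssociationTable: directed bipartite edges from an entity to another
#'
#' Holds one of the four edge tables the pipeline consumes: formula to herb,
#' herb to compound, compound to target gene, or drug to target gene. Edges
#' are deduplicated at construction; the number of collapsed duplicate rows is
#' retained so that association counts and distinct-target counts can both be
#' reported (they genuinely differ in curated herb-target data).
#'
#' @slot kind one of \code{"formula_herb"}, \code{"herb_compound"},
#'   \code{"compound_target"}, \code{"drug_target"}
#' @slot edges two-column \code{data.frame} with columns \code{source},
#'   \code{target}; no duplicated rows
#' @slot nDuplicates number of duplicate input rows collapsed on load
#' @exportClass AssociationTable
setClass("AssociationTable",
  representation(
    kind        = "character",
    edges       = "data.frame",
    nDuplicates = "integer"
  )
)

setValidity("AssociationTable", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .assocKinds)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.assocKinds, collapse = ", ")))
  if (!identical(colnames(object@edges), c("source", "target")))
    msg <- c(msg, "edges must have columns 'source' and 'target'")
  else {
    if (anyDuplicated(object@edges))
      msg <- c(msg, "edges contains duplicate (source, target) pairs")
    if (nrow(object@edges) > 0 &&
        (any(!nzchar(object@edges$source)) || any(!nzchar(object@edges$target))))
      msg <- c(msg, "edges contains empty ids")
  }
  if (length(msg)) msg else TRUE
})

#' AdmetTable: per-compound ADMET annotations
#'
#' One row per compound with categorical predictions for AMES mutagenicity,
#' carcinogenicity, and hERG channel inhibition. Blank or missing cells are
#' represented as \code{"unknown"}.
#'
#' @slot annotations \code{data.frame} with columns \code{compound_id},
#'   \code{ames}, \code{carcinogenicity}, \code{herg}, each categorical column
#'   restricted to its closed vocabulary
#' @exportClass AdmetTable
setClass("AdmetTable", representation(annotations = "data.frame"))

setValidity("AdmetTable", function(object) {
  ann <- object@annotations
  need <- c("compound_id", "ames", "carcinogenicity", "herg")
  if (!all(need %in% colnames(ann)))
    return(sprintf("annotations must have columns: %s", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(ann$compound_id))
    msg <- c(msg, "duplicated compound_id")
  if (!all(ann$ames %in% .amesLevels))
    msg <- c(msg, "ames value outside vocabulary")
  if (!all(ann$carcinogenicity %in% .carcLevels))
    msg <- c(msg, "carcinogenicity value outside vocabulary")
  if (!all(ann$herg %in% .hergLevels))
    msg <- c(msg, "herg value outside vocabulary")
  if (length(msg)) msg else TRUE
})

#' ModuleDefinition: a labelled set of drugs with a role
#'
#' A drug module is either the main-indication module (the drugs known to
#' treat the disease under study) or a side-effect module (drugs treating one
#' named side effect of the main module).
#'
#' @slot moduleId module identifier
#' @slot diseaseLabel human-readable indication label (used in report rows)
#' @slot role \code{"main"} or \code{"side_effect"}
#' @slot drugIds non-empty character vector of drug identifiers
#' @exportClass ModuleDefinition
setClass("ModuleDefinition",
  representation(
    moduleId     = "character",
    diseaseLabel = "character",
    role         = "character",
    drugIds      = "character"
  )
)

setValidity("ModuleDefinition", function(object) {
  msg <- character()
  if (length(object@moduleId) != 1L || !nzchar(object@moduleId))
    msg <- c(msg, "moduleId must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% .moduleRoles)
    msg <- c(msg, "role must be 'main' or 'side_effect'")
  if (length(object@drugIds) == 0L || any(!nzchar(object@drugIds)))
    msg <- c(msg, "drugIds must be non-empty")
  if (anyDuplicated(object@drugIds))
    msg <- c(msg, "drugIds must be unique")
  if (length(msg)) msg else TRUE
})

#' FilterRuleSet: which ADMET exclusion rules are active
#'
#' The three rules mirror the predicted-value triggers used to triage herbal
#' ingredients: AMES \code{"toxic"}, carcinogenicity \code{"danger"}, and hERG
#' \code{"inhibitor"} or \code{"strong inhibitor"}. Compounds with no
#' annotation row are governed by \code{unknownPolicy}.
#'
#' @slot excludeAmes drop compounds predicted AMES-toxic
#' @slot excludeCarcinogenicity drop compounds predicted carcinogenic
#' @slot excludeHerg drop hERG inhibitors and strong inhibitors
#' @slot unknownPolicy \code{"keep"} (default) or \code{"drop"} for compounds
#'   without an annotation row
#' @exportClass FilterRuleSet
setClass("FilterRuleSet",
  representation(
    excludeAmes            = "logical",
    excludeCarcinogenicity = "logical",
    excludeHerg            = "logical",
    unknownPolicy          = "character"
  )
)

setValidity("FilterRuleSet", function(object) {
  if (!object@unknownPolicy %in% c("keep", "drop"))
    return("unknownPolicy must be 'keep' or 'drop'")
  TRUE
})

#' TargetSpace: a deduplicated set of normalized gene symbols with provenance
#'
#' The central object of the analysis: the set of genes targeted by all kept
#' compounds of a formula (or herb), by all drugs of a module, or by a random
#' draw from a gene universe. Provenance tags record which filters produced
#' the set.
#'
#' @slot ownerId identifier of the owning entity
#' @slot ownerKind \code{"formula"}, \code{"herb"}, \code{"drug_module"}, or
#'   \code{"random"}
#' @slot genes sorted character vector of distinct normalized gene symbols
#' @slot filtersApplied tags such as \code{"cyp_excluded"},
#'   \code{"admet_filtered"}
#' @exportClass TargetSpace
setClass("TargetSpace",
  representation(
    ownerId        = "character",
    ownerKind      = "character",
    genes          = "character",
    filtersApplied = "character"
  )
)

setValidity("TargetSpace", function(object) {
  msg <- character()
  if (!object@ownerKind %in% c("formula", "herb", "drug_module", "random"))
    msg <- c(msg, "ownerKind must be formula, herb, drug_module, or random")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "genes must be distinct")
  if ("cyp_excluded" %in% object@filtersApplied && any(isCyp(object@genes)))
    msg <- c(msg, "space tagged cyp_excluded still contains CYP isozyme symbols")
  if (length(msg)) msg else TRUE
})

#' SupportResult: overlap of a drug space with a formula space
#'
#' Support is the fraction of the drug module's target space that the formula's
#' target space covers: |X intersect Y| / |X| with X the drug space in the
#' denominator role.
#'
#' @slot drugId identifier of the drug-space owner (module id)
#' @slot formulaId identifier of the formula-space owner
#' @slot drugSpaceSize |X|, at least 1
#' @slot formulaSpaceSize |Y|
#' @slot overlapGenes lexicographically sorted genes in X intersect Y
#' @slot support |overlap| / |X|, exactly
#' @exportClass SupportResult
setClass("SupportResult",
  representation(
    drugId           = "character",
    formulaId        = "character",
    drugSpaceSize    = "integer",
    formulaSpaceSize = "integer",
    overlapGenes     = "character",
    support          = "numeric"
  )
)

setValidity("SupportResult", function(object) {
  msg <- character()
  if (object@drugSpaceSize < 1L)
    msg <- c(msg, "drugSpaceSize must be >= 1")
  if (object@formulaSpaceSize < 0L)
    msg <- c(msg, "formulaSpaceSize must be >= 0")
  if (length(object@overlapGenes) > min(object@drugSpaceSize, object@formulaSpaceSize))
    msg <- c(msg, "overlap larger than an input space")
  if (!identical(object@support,
                 length(object@overlapGenes) / object@drugSpaceSize))
    msg <- c(msg, "support must equal |overlap| / drugSpaceSize exactly")
  if (is.unsorted(object@overlapGenes))
    msg <- c(msg, "overlapGenes must be sorted")
  if (length(msg)) msg else TRUE
})

#' WeightedScore: convex aggregation of per-module supports
#'
#' The main-indication support receives \code{mainWeight} (default 0.5) and the
#' remaining weight is split equally across the side-effect modules. With no
#' side-effect modules the weighted average equals the main support.
#'
#' @slot formulaId formula identifier
#' @slot mainModuleId id of the main-indication module
#' @slot mainSupport support against the main-indication module
#' @slot sideModuleIds side-effect module ids, in input order
#' @slot sideSupports supports against the side-effect modules, same order
#' @slot weights convex weights (main first), summing to 1
#' @slot weightedAverage the aggregate score
#' @exportClass WeightedScore
setClass("WeightedScore",
  representation(
    formulaId       = "character",
    mainModuleId    = "character",
    mainSupport     = "numeric",
    sideModuleIds   = "character",
    sideSupports    = "numeric",
    weights         = "numeric",
    weightedAverage = "numeric"
  )
)

setValidity("WeightedScore", function(object) {
  msg <- character()
  s <- c(object@mainSupport, object@sideSupports)
  if (any(s < 0 | s > 1))
    msg <- c(msg, "supports must lie in [0, 1]")
  if (length(object@weights) != length(s))
    msg <- c(msg, "one weight per support required")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 (within 1e-12)")
  if (length(object@sideModuleIds) != length(object@sideSupports))
    msg <- c(msg, "sideModuleIds and sideSupports lengths differ")
  w <- object@weightedAverage
  if (w < min(s) - 1e-12 || w > max(s) + 1e-12)
    msg <- c(msg, "weightedAverage must lie between min and max support")
  if (length(msg)) msg else TRUE
})

#' GeneUniverse: pool of genes random target spaces are drawn from
#'
#' @slot genes distinct normalized gene symbols
#' @slot sourceTag free-text provenance (e.g. file name, "drug_target union")
#' @exportClass GeneUniverse
setClass("GeneUniverse",
  representation(genes = "character", sourceTag = "character"))

setValidity("GeneUniverse", function(object) {
  if (anyDuplicated(object@genes)) "genes must be distinct" else TRUE
})

#' NullDistribution: supports of random same-cardinality target spaces
#'
#' Summarises \code{nDraws} supports computed with a uniformly drawn k-gene
#' random space in the drug-space (denominator) role against a fixed formula
#' space. Mean and variance use the population convention (divide by
#' \code{nDraws}). \code{empiricalP} is the add-one upper-tail permutation p of
#' \code{observed} against the draws, populated only when an observed support
#' was supplied.
#'
#' @slot formulaId formula whose space was held fixed
#' @slot k cardinality of each random space
#' @slot nDraws number of independent draws
#' @slot supports the \code{nDraws} support values
#' @slot mean arithmetic mean of \code{supports}
#' @slot variance population variance of \code{supports}
#' @slot observed observed support being calibrated (NA if none supplied)
#' @slot empiricalP add-one permutation p (NA if no observed support)
#' @slot seed integer seed the draws were generated from
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(
    formulaId  = "character",
    k          = "integer",
    nDraws     = "integer",
    supports   = "numeric",
    mean       = "numeric",
    variance   = "numeric",
    observed   = "numeric",
    empiricalP = "numeric",
    seed       = "integer"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@supports) != object@nDraws)
    msg <- c(msg, "length(supports) must equal nDraws")
  if (any(object@supports < 0 | object@supports > 1))
    msg <- c(msg, "supports must lie in [0, 1]")
  if (abs(object@mean - mean(object@supports)) > 1e-12)
    msg <- c(msg, "mean inconsistent with supports")
  v <- mean((object@supports - mean(object@supports))^2)
  if (abs(object@variance - v) > 1e-12)
    msg <- c(msg, "variance inconsistent with supports (population convention)")
  if (!is.na(object@empiricalP) &&
      (object@empiricalP <= 0 || object@empiricalP > 1))
    msg <- c(msg, "empiricalP must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic dataset generator
#'
#' Describes a synthetic study: a gene universe, formulas with herb/compound
#' structure, drug modules (first one main), and the exact number of genes
#' planted in common between each formula's space and each module's space.
#'
#' @slot universeSize number of genes in the synthetic universe
#' @slot nFormulas number of formulas to generate
#' @slot herbsPerFormula length-2 integer range (min, max)
#' @slot compoundsPerHerb length-2 integer range (min, max)
#' @slot formulaSpaceSize number of genes in each formula's planted space
#' @slot moduleSizes one size per drug module; first module is the main one
#' @slot moduleLabels disease labels, same length as moduleSizes
#' @slot plantedOverlaps genes shared between each formula space and each
#'   module space, same length as moduleSizes
#' @slot toxicFraction fraction of compounds flagged AMES-toxic
#' @slot cypFraction fraction of universe genes given CYP-isozyme-style names
#' @slot redundancy number of compounds each planted formula gene is assigned
#'   to (1 = exclusion of one compound removes its genes predictably)
#' @slot seed integer seed
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    universeSize     = "integer",
    nFormulas        = "integer",
    herbsPerFormula  = "integer",
    compoundsPerHerb = "integer",
    formulaSpaceSize = "integer",
    moduleSizes      = "integer",
    moduleLabels     = "character",
    plantedOverlaps  = "integer",
    toxicFraction    = "numeric",
    cypFraction      = "numeric",
    redundancy       = "integer",
    seed             = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@moduleSizes) < 1L)
    msg <- c(msg, "at least one module (the main one) is required")
  if (length(object@plantedOverlaps) != length(object@moduleSizes))
    msg <- c(msg, "plantedOverlaps must have one entry per module")
  else if (any(object@plantedOverlaps >
               pmin(object@formulaSpaceSize, object@moduleSizes)))
    msg <- c(msg, "plantedOverlaps[i] must be <= min(formulaSpaceSize, moduleSizes[i])")
  if (length(object@moduleLabels) != length(object@moduleSizes))
    msg <- c(msg, "moduleLabels must have one entry per module")
  if (object@formulaSpaceSize > object@universeSize ||
      any(object@moduleSizes > object@universeSize))
    msg <- c(msg, "space sizes cannot exceed universeSize")
  if (length(object@herbsPerFormula) != 2L || length(object@compoundsPerHerb) != 2L ||
      any(object@herbsPerFormula < 1L) || any(object@compoundsPerHerb < 1L) ||
      diff(object@herbsPerFormula) < 0L || diff(object@compoundsPerHerb) < 0L)
    msg <- c(msg, "herbsPerFormula and compoundsPerHerb must be increasing ranges >= 1")
  if (object@toxicFraction < 0 || object@toxicFraction > 1 ||
      object@cypFraction < 0 || object@cypFraction > 1)
    msg <- c(msg, "toxicFraction and cypFraction must lie in [0, 1]")
  if (object@redundancy < 1L)
    msg <- c(msg, "redundancy must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable [%s]: %d edges, %d sources, %d targets (%d duplicate rows collapsed)\n",
              object@kind, nrow(object@edges),
              length(unique(object@edges$source)),
              length(unique(object@edges$target)),
              object@nDuplicates))
})

setMethod("show", "TargetSpace", function(object) {
  cat(sprintf("TargetSpace of %s '%s': %d genes%s\n",
              object@ownerKind, object@ownerId, length(object@genes),
              if (length(object@filtersApplied))
                sprintf(" [%s]", paste(object@filtersApplied, collapse = ", "))
              else ""))
  if (length(object@genes))
    cat("  ", paste(utils::head(object@genes, 8), collapse = ", "),
        if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SupportResult", function(object) {
  cat(sprintf("SupportResult %s -> %s: support %.4f (%d of %d drug targets covered)\n",
              object@drugId, object@formulaId, object@support,
              length(object@overlapGenes), object@drugSpaceSize))
})

setMethod("show", "WeightedScore", function(object) {
  cat(sprintf("WeightedScore for formula '%s': %.4f (main %.4f, %d side module%s)\n",
              object@formulaId, object@weightedAverage, object@mainSupport,
              length(object@sideSupports),
              if (length(object@sideSupports) == 1L) "" else "s"))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution for '%s': %d draws of k=%d, mean %.4f, variance %.4g",
              object@formulaId, object@nDraws, object@k, object@mean,
              object@variance))
  if (!is.na(object@empiricalP))
    cat(sprintf(", observed %.4f (empirical p = %.4g)", object@observed,
                object@empiricalP))
  cat("\n")
})

setMethod("show", "GeneUniverse", function(object) {
  cat(sprintf("GeneUniverse '%s': %d genes\n", object@sourceTag,
              length(object@genes)))
})

setMethod("show", "ModuleDefinition", function(object) {
  cat(sprintf("ModuleDefinition '%s' (%s, role %s): %d drugs\n",
              object@moduleId, object@diseaseLabel, object@role,
              length(object@drugIds)))
})
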