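#' @describeIn support Support of one target space against another: the size
#'   of the intersection divided by the size of the drug space, an exact
#'   rational held at full floating precision. The drug space must be
#'   non-empty (it is the denominator); the overlap gene list is stored
#'   sorted lexicographically.
#' @examples
#' x <- new("TargetSpace", ownerId = "m", ownerKind = "drug_module",
#'          genes = c("A", "B", "C", "D"), filtersApplied = character())
#' y <- new("TargetSpace", ownerId = "f", ownerKind = "formula",
#'          genes = c("A", "B"), filtersApplied = character())
#' supportValue(support(x, y))  # 0.5
#' @export
setMethod("support", signature("TargetSpace", "TargetSpace"),
  function(drugSpace, formulaSpace) {
    nx <- length(drugSpace@genes)
    if (nx == 0L)
      stop(sprintf("drug space '%s' is empty: support undefined",
                   drugSpace@ownerId))
    ov <- sort(intersect(drugSpace@genes, formulaSpace@genes))
    new("SupportResult",
        drugId = drugSpace@ownerId,
        formulaId = formulaSpace@ownerId,
        drugSpaceSize = nx,
        formulaSpaceSize = length(formulaSpace@genes),
        overlapGenes = ov,
        support = length(ov) / nx)
  })

#' Weighted-average aggregation of per-module supports
#'
#' The overall score of a formula combines its support against the
#' main-indication drug module with its supports against the side-effect
#' modules. The main support carries \code{mainWeight} (default 0.5, i.e.
#' 50\%); the remaining weight is split equally across the \code{m}
#' side-effect modules, so each side support is weighted
#' \code{(1 - mainWeight) / m}. With no side modules the score is the main
#' support itself. The result is convex: it always lies between the smallest
#' and largest input support, and equals the plain arithmetic mean when
#' \code{mainWeight = 1 / (m + 1)}.
#'
#' @param mainSupport support against the main-indication module, in [0, 1]
#' @param sideSupports numeric vector of side-module supports, in [0, 1]
#' @param mainWeight weight of the main support, in [0, 1] (default 0.5)
#' @param formulaId optional formula identifier carried into the result
#' @param mainModuleId,sideModuleIds optional module ids for reporting
#' @return a \linkS4class{WeightedScore}
#' @examples
#' # one main support and four side supports, half the weight on the main one
#' weightedAvg(weightedAverage(0.63, c(0.44, 0.66, 0.5, 0.69)))  # 0.60125
#' @export
weightedAverage <- function(mainSupport, sideSupports = numeric(),
                            mainWeight = 0.5, formulaId = "formula",
                            mainModuleId = "main",
                            sideModuleIds = NULL) {
  s <- c(mainSupport, sideSupports)
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("all supports must lie in [0, 1]")
  if (length(mainSupport) != 1L)
    stop("mainSupport must be a single value")
  if (is.na(mainWeight) || mainWeight < 0 || mainWeight > 1)
    stop("mainWeight must lie in [0, 1]")
  m <- length(sideSupports)
  if (is.null(sideModuleIds))
    sideModuleIds <- if (m) sprintf("side%d", seq_len(m)) else character()
  if (length(sideModuleIds) != m)
    stop("sideModuleIds must match sideSupports in length")
  if (m == 0L) {
    weights <- 1
    w <- mainSupport
  } else {
    weights <- c(mainWeight, rep((1 - mainWeight) / m, m))
    w <- sum(weights * s)
  }
  new("WeightedScore",
      formulaId = formulaId,
      mainModuleId = mainModuleId,
      mainSupport = as.numeric(mainSupport),
      sideModuleIds = as.character(sideModuleIds),
      sideSupports = as.numeric(sideSupports),
      weights = weights,
      weightedAverage = w)
}

#' Score a formula against a set of drug modules
#'
#' Computes one support per (module, formula) pair and assembles the
#' weighted score: the module with role \code{main} provides the main
#' support, the side-effect modules (in input order) the side supports.
#'
#' @param formulaSpace the formula's \linkS4class{TargetSpace}
#' @param modules list of \code{list(def = ModuleDefinition, space =
#'   TargetSpace)} pairs; exactly one definition must have role \code{main}
#' @param mainWeight weight of the main-module support (default 0.5)
#' @return list with \code{supports} (list of \linkS4class{SupportResult},
#'   in module order) and \code{score} (a \linkS4class{WeightedScore})
#' @export
compareFormulaToModules <- function(formulaSpace, modules, mainWeight = 0.5) {
  roles <- vapply(modules, function(m) m$def@role, "")
  if (sum(roles == "main") != 1L)
    stop(sprintf("exactly one module with role=main required, found %d",
                 sum(roles == "main")))
  supports <- lapply(modules, function(m) support(m$space, formulaSpace))
  vals <- vapply(supports, function(sr) sr@support, 0)
  ids <- vapply(modules, function(m) m$def@moduleId, "")
  mainIdx <- which(roles == "main")
  score <- weightedAverage(
    mainSupport = vals[mainIdx],
    sideSupports = vals[-mainIdx],
    mainWeight = mainWeight,
    formulaId = formulaSpace@ownerId,
    mainModuleId = ids[mainIdx],
    sideModuleIds = ids[-mainIdx])
  list(supports = supports, score = score)
}
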