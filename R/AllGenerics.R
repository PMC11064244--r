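#' Accessor generics
#'
#' Small accessor layer over the S4 classes so user code never touches slots.
#'
#' @param x an object of one of the package's S4 classes
#' @return the slot value; see each method's class documentation
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("ownerId", function(x) standardGeneric("ownerId"))

#' @rdname accessors
#' @export
setGeneric("ownerKind", function(x) standardGeneric("ownerKind"))

#' @rdname accessors
#' @export
setGeneric("filtersApplied", function(x) standardGeneric("filtersApplied"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("assocKind", function(x) standardGeneric("assocKind"))

#' @rdname accessors
#' @export
setGeneric("duplicatesCollapsed", function(x) standardGeneric("duplicatesCollapsed"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' @rdname accessors
#' @export
setGeneric("diseaseLabel", function(x) standardGeneric("diseaseLabel"))

#' @rdname accessors
#' @export
setGeneric("moduleRole", function(x) standardGeneric("moduleRole"))

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname accessors
#' @export
setGeneric("supportValue", function(x) standardGeneric("supportValue"))

#' @rdname accessors
#' @export
setGeneric("overlapGenes", function(x) standardGeneric("overlapGenes"))

#' @rdname accessors
#' @export
setGeneric("weightedAvg", function(x) standardGeneric("weightedAvg"))

#' @rdname accessors
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname accessors
#' @export
setGeneric("nullSupports", function(x) standardGeneric("nullSupports"))

#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setGeneric("nullVariance", function(x) standardGeneric("nullVariance"))

#' Support of a drug target space against a formula target space
#'
#' @param drugSpace a \linkS4class{TargetSpace} in the denominator role
#' @param formulaSpace a \linkS4class{TargetSpace}
#' @return a \linkS4class{SupportResult}
#' @export
setGeneric("support", function(drugSpace, formulaSpace) standardGeneric("support"))

## ---- accessor methods ------------------------------------------------------

#' @rdname accessors
setMethod("genes", "TargetSpace", function(x) x@genes)
#' @rdname accessors
setMethod("genes", "GeneUniverse", function(x) x@genes)
#' @rdname accessors
setMethod("ownerId", "TargetSpace", function(x) x@ownerId)
#' @rdname accessors
setMethod("ownerKind", "TargetSpace", function(x) x@ownerKind)
#' @rdname accessors
setMethod("filtersApplied", "TargetSpace", function(x) x@filtersApplied)
#' @rdname accessors
setMethod("edges", "AssociationTable", function(x) x@edges)
#' @rdname accessors
setMethod("assocKind", "AssociationTable", function(x) x@kind)
#' @rdname accessors
setMethod("duplicatesCollapsed", "AssociationTable", function(x) x@nDuplicates)
#' @rdname accessors
setMethod("annotations", "AdmetTable", function(x) x@annotations)
#' @rdname accessors
setMethod("moduleId", "ModuleDefinition", function(x) x@moduleId)
#' @rdname accessors
setMethod("diseaseLabel", "ModuleDefinition", function(x) x@diseaseLabel)
#' @rdname accessors
setMethod("moduleRole", "ModuleDefinition", function(x) x@role)
#' @rdname accessors
setMethod("drugIds", "ModuleDefinition", function(x) x@drugIds)
#' @rdname accessors
setMethod("supportValue", "SupportResult", function(x) x@support)
#' @rdname accessors
setMethod("overlapGenes", "SupportResult", function(x) x@overlapGenes)
#' @rdname accessors
setMethod("supportValue", "WeightedScore",
          function(x) c(x@mainSupport, x@sideSupports))
#' @rdname accessors
setMethod("weightedAvg", "WeightedScore", function(x) x@weightedAverage)
#' @rdname accessors
setMethod("scoreWeights", "WeightedScore", function(x) x@weights)
#' @rdname accessors
setMethod("nullSupports", "NullDistribution", function(x) x@supports)
#' @rdname accessors
setMethod("nullMean", "NullDistribution", function(x) x@mean)
#' @rdname accessors
setMethod("nullVariance", "NullDistribution", function(x) x@variance)
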