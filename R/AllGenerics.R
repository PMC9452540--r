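#' Accessors for package classes
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x a `ReferenceCatalog`, `ConditionProfile` or `ComparisonResult`
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))

#' @rdname accessors
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))

#' @rdname accessors
#' @export
setGeneric("mirnaArm", function(x) standardGeneric("mirnaArm"))

#' @rdname accessors
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("maxTailLength", function(x) standardGeneric("maxTailLength"))

#' @rdname accessors
#' @export
setGeneric("motifIndex", function(x) standardGeneric("motifIndex"))

#' @rdname accessors
#' @export
setGeneric("mirnaMetrics", function(x) standardGeneric("mirnaMetrics"))

#' @rdname accessors
#' @export
setGeneric("lengthIdentity", function(x) standardGeneric("lengthIdentity"))

#' @rdname accessors
#' @export
setGeneric("totalAssigned", function(x) standardGeneric("totalAssigned"))

#' @rdname accessors
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

#' @rdname accessors
#' @export
setGeneric("replicateName", function(x) standardGeneric("replicateName"))

#' @rdname accessors
#' @export
setGeneric("isomirFoldChanges", function(x) standardGeneric("isomirFoldChanges"))

#' @rdname accessors
#' @export
setGeneric("mirnaFoldChanges", function(x) standardGeneric("mirnaFoldChanges"))

#' @rdname accessors
#' @export
setGeneric("tailingCurves", function(x) standardGeneric("tailingCurves"))

#' @rdname accessors
#' @export
setMethod("mirnaNames", "ReferenceCatalog", function(x) names(x@mature))

#' @rdname accessors
#' @export
setMethod("matureSeqs", "ReferenceCatalog", function(x) x@mature)

#' @rdname accessors
#' @export
setMethod("mirnaArm", "ReferenceCatalog", function(x) x@arm)

#' @rdname accessors
#' @export
setMethod("lociTable", "ReferenceCatalog", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("motifLength", "ReferenceCatalog", function(x) x@motifLen)

#' @rdname accessors
#' @export
setMethod("maxTailLength", "ReferenceCatalog", function(x) x@maxTailLen)

#' @rdname accessors
#' @export
setMethod("motifIndex", "ReferenceCatalog", function(x) {
  split(names(x@motifs), x@motifs)
})

#' @rdname accessors
#' @export
setMethod("mirnaMetrics", "ConditionProfile", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("lengthIdentity", "ConditionProfile", function(x) x@lenIdentity)

#' @rdname accessors
#' @export
setMethod("totalAssigned", "ConditionProfile", function(x) x@totalAssigned)

#' @rdname accessors
#' @export
setMethod("conditionName", "ConditionProfile", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("replicateName", "ConditionProfile", function(x) x@replicate)

#' @rdname accessors
#' @export
setMethod("isomirFoldChanges", "ComparisonResult", function(x) x@isomirFC)

#' @rdname accessors
#' @export
setMethod("mirnaFoldChanges", "ComparisonResult", function(x) x@mirnaFC)

#' @rdname accessors
#' @export
setMethod("tailingCurves", "ComparisonResult", function(x) x@curves)
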