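## Accessor generics for the core containers. Slot access from user code is
## discouraged; these are the supported surface.

#' @rdname accessors
#' @param object a treking S4 object
#' @export
setGeneric("plateTimes", function(object) standardGeneric("plateTimes"))
#' @rdname accessors
#' @export
setGeneric("plateWells", function(object) standardGeneric("plateWells"))
#' @rdname accessors
#' @export
setGeneric("plateValues", function(object) standardGeneric("plateValues"))
#' @rdname accessors
#' @export
setGeneric("plateAnnotations", function(object) standardGeneric("plateAnnotations"))
#' @rdname accessors
#' @export
setGeneric("windowMidpoints", function(object) standardGeneric("windowMidpoints"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("windowEnds", function(object) standardGeneric("windowEnds"))
#' @rdname accessors
#' @export
setGeneric("rawAUC", function(object) standardGeneric("rawAUC"))
#' @rdname accessors
#' @export
setGeneric("normalizedAUC", function(object) standardGeneric("normalizedAUC"))
#' @rdname accessors
#' @export
setGeneric("controlId", function(object) standardGeneric("controlId"))
#' @rdname accessors
#' @export
setGeneric("windowGrid", function(object) standardGeneric("windowGrid"))
#' @rdname accessors
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))
#' @rdname accessors
#' @export
setGeneric("functionalityCalls", function(object) standardGeneric("functionalityCalls"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("neuronTable", function(object) standardGeneric("neuronTable"))
#' @rdname accessors
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setGeneric("networkMembers", function(object) standardGeneric("networkMembers"))

#' Accessors for treking containers
#'
#' Read-only accessors for the slots of the package's S4 classes.
#'
#' @name accessors
#' @return the corresponding slot value
NULL

#' @rdname accessors
setMethod("plateTimes", "TimeSeriesPlate", function(object) object@times)
#' @rdname accessors
setMethod("plateWells", "TimeSeriesPlate", function(object) object@wells)
#' @rdname accessors
setMethod("plateValues", "TimeSeriesPlate", function(object) object@values)
#' @rdname accessors
setMethod("plateAnnotations", "TimeSeriesPlate", function(object) object@annotations)
#' @rdname accessors
setMethod("windowMidpoints", "WindowGrid", function(object) object@midpoints)
#' @rdname accessors
setMethod("windowStarts", "WindowGrid", function(object) object@starts)
#' @rdname accessors
setMethod("windowEnds", "WindowGrid", function(object) object@ends)
#' @rdname accessors
setMethod("windowMidpoints", "AUCMatrix", function(object) object@grid@midpoints)
#' @rdname accessors
setMethod("rawAUC", "AUCMatrix", function(object) object@raw)
#' @rdname accessors
setMethod("normalizedAUC", "AUCMatrix", function(object) object@normalized)
#' @rdname accessors
setMethod("controlId", "AUCMatrix", function(object) object@controlId)
#' @rdname accessors
setMethod("windowGrid", "AUCMatrix", function(object) object@grid)
#' @rdname accessors
setMethod("windowGrid", "FunctionalityMatrix", function(object) object@grid)
#' @rdname accessors
setMethod("activityMatrix", "KinaseActivityPanel", function(object) object@activity)
#' @rdname accessors
setMethod("functionalityCalls", "FunctionalityMatrix", function(object) object@calls)
#' @rdname accessors
setMethod("codebook", "SOMMap", function(object) object@codebook)
#' @rdname accessors
setMethod("neuronTable", "NeuronAssignment", function(object) object@assignment)
#' @rdname accessors
setMethod("networkGraph", "BackgroundNetwork", function(object) object@graph)
#' @rdname accessors
setMethod("networkGraph", "LocalNetwork", function(object) object@graph)
#' @rdname accessors
setMethod("networkMembers", "LocalNetwork", function(object) object@members)

`%||%` <- function(a, b) if (is.null(a)) b else a
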