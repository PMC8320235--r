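#' @name accessors
#' @title Accessors for epilink result objects
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than `@`.
#' @param object An epilink S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("endpoints", function(object) standardGeneric("endpoints"))
#' @rdname accessors
#' @export
setMethod("endpoints", "ConformationBatch", function(object) object@endpoints)

#' @rdname accessors
#' @export
setGeneric("chainVertices", function(object) standardGeneric("chainVertices"))
#' @rdname accessors
#' @export
setMethod("chainVertices", "ConformationBatch", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("nAccepted", function(object) standardGeneric("nAccepted"))
#' @rdname accessors
#' @export
setMethod("nAccepted", "ConformationBatch", function(object) object@nAccepted)

#' @rdname accessors
#' @export
setGeneric("nAttempted", function(object) standardGeneric("nAttempted"))
#' @rdname accessors
#' @export
setMethod("nAttempted", "ConformationBatch", function(object) object@nAttempted)

#' @rdname accessors
#' @export
setGeneric("radialPeak", function(object) standardGeneric("radialPeak"))
#' @rdname accessors
#' @export
setMethod("radialPeak", "RadialDistribution", function(object) object@peak)

#' @rdname accessors
#' @export
setGeneric("radialFwhm", function(object) standardGeneric("radialFwhm"))
#' @rdname accessors
#' @export
setMethod("radialFwhm", "RadialDistribution", function(object) object@fwhm)

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setMethod("binEdges", "RadialDistribution", function(object) object@binEdges)

#' @rdname accessors
#' @export
setGeneric("radialDensity", function(object) standardGeneric("radialDensity"))
#' @rdname accessors
#' @export
setMethod("radialDensity", "RadialDistribution", function(object) object@density)

#' @rdname accessors
#' @export
setGeneric("kernelValues", function(object) standardGeneric("kernelValues"))
#' @rdname accessors
#' @export
setMethod("kernelValues", "CompoundKernel", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("shellRadius", function(object) standardGeneric("shellRadius"))
#' @rdname accessors
#' @export
setMethod("shellRadius", "RingFit", function(object) object@r)

#' @rdname accessors
#' @export
setGeneric("shellWidth", function(object) standardGeneric("shellWidth"))
#' @rdname accessors
#' @export
setMethod("shellWidth", "RingFit", function(object) object@w)

#' @rdname accessors
#' @export
setGeneric("shellSigma", function(object) standardGeneric("shellSigma"))
#' @rdname accessors
#' @export
setMethod("shellSigma", "RingFit", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("ci95", function(object) standardGeneric("ci95"))
#' @rdname accessors
#' @export
setMethod("ci95", "RingFit", function(object)
  c(r = object@ci95R, w = object@ci95W))
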