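#' @rdname MarkerMatrix-class
#' @param x,object a package object
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' @rdname GMMModel-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname GMMModel-class
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname GMMModel-class
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))

#' @rdname GMMModel-class
#' @export
setGeneric("componentSigmas", function(x) standardGeneric("componentSigmas"))

#' @rdname GMMModel-class
#' @export
setGeneric("bicTrace", function(x) standardGeneric("bicTrace"))

#' @rdname MembershipFunctionSet-class
#' @export
setGeneric("retainedComponents", function(x) standardGeneric("retainedComponents"))

#' @rdname ExpandedMatrix-class
#' @export
setGeneric("featureProvenance", function(x) standardGeneric("featureProvenance"))
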