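#' Construct a MarkerMatrix
#'
#' @param values numeric matrix (cells x markers).
#' @param markerNames marker names; defaults to \code{colnames(values)}.
#' @param cellLabels optional per-cell population labels.
#' @param batchIds optional per-cell batch identifiers.
#' @param transformed whether values are already arcsinh-transformed.
#' @param nDropped number of rows dropped upstream for non-finite values.
#' @return a [MarkerMatrix-class]
#' @examples
#' m <- markerMatrix(matrix(rnorm(20), 10, 2,
#'                          dimnames = list(NULL, c("CD45", "B220"))))
#' markerNames(m)
#' @export
markerMatrix <- function(values, markerNames = colnames(values),
                         cellLabels = NULL, batchIds = NULL,
                         transformed = FALSE, nDropped = 0L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(markerNames)) colnames(values) <- markerNames
  new("MarkerMatrix", values = values,
      cellLabels = if (is.null(cellLabels)) character(0) else as.character(cellLabels),
      batchIds = if (is.null(batchIds)) character(0) else as.character(batchIds),
      transformed = transformed, nDropped = as.integer(nDropped))
}

#' Construct a GMMModel directly from parameters
#'
#' Mostly useful for tests and for evaluating posterior curves of a known
#' mixture; [fitMarkerGMM()] is the estimation entry point.
#'
#' @param weights,means,sigmas component parameters (relabeled to
#'   ascending-mean order internally).
#' @param markerName marker the model describes.
#' @param dataRange observed [min, max]; defaults to means +/- 4 sigmas span.
#' @param sigmaMin sigma floor recorded with the model.
#' @param nObs,seed,bicTrace,logLik,componentIndex,fitInfo metadata.
#' @return a [GMMModel-class]
#' @export
gmmModel <- function(weights, means, sigmas, markerName = "marker",
                     dataRange = NULL, sigmaMin = min(sigmas),
                     nObs = 0L, seed = 0L, bicTrace = numeric(0),
                     logLik = NA_real_, componentIndex = NULL,
                     fitInfo = list()) {
  K <- length(means)
  ord <- orderComponents(means, sigmas, weights)
  if (is.null(dataRange)) {
    dataRange <- c(min(means - 4 * sigmas), max(means + 4 * sigmas))
  }
  if (is.null(componentIndex)) componentIndex <- seq_len(K)
  new("GMMModel", markerName = markerName, K = as.integer(K),
      weights = weights[ord] / sum(weights), means = means[ord],
      sigmas = sigmas[ord], nObs = as.integer(nObs),
      bicTrace = bicTrace, logLik = logLik, seed = as.integer(seed),
      sigmaMin = sigmaMin, dataRange = as.numeric(dataRange),
      componentIndex = as.integer(componentIndex[ord]), fitInfo = fitInfo)
}

#' @rdname MarkerMatrix-class
#' @export
setMethod("intensityValues", "MarkerMatrix", function(x) x@values)

#' @rdname ExpandedMatrix-class
#' @export
setMethod("intensityValues", "ExpandedMatrix", function(x) x@values)

#' @rdname MarkerMatrix-class
#' @export
setMethod("markerNames", "MarkerMatrix", function(x) colnames(x@values))

#' @rdname MarkerMatrix-class
#' @export
setMethod("cellLabels", "MarkerMatrix",
          function(x) if (length(x@cellLabels)) x@cellLabels else NULL)

#' @rdname ExpandedMatrix-class
#' @export
setMethod("cellLabels", "ExpandedMatrix",
          function(x) if (length(x@cellLabels)) x@cellLabels else NULL)

#' @rdname MarkerMatrix-class
#' @export
setMethod("isTransformed", "MarkerMatrix", function(x) x@transformed)

#' @rdname MarkerMatrix-class
#' @export
setMethod("dim", "MarkerMatrix", function(x) dim(x@values))

#' @rdname ExpandedMatrix-class
#' @export
setMethod("dim", "ExpandedMatrix", function(x) dim(x@values))

#' @rdname GMMModel-class
#' @export
setMethod("nComponents", "GMMModel", function(x) x@K)

#' @rdname GMMModel-class
#' @export
setMethod("componentWeights", "GMMModel", function(x) x@weights)

#' @rdname GMMModel-class
#' @export
setMethod("componentMeans", "GMMModel", function(x) x@means)

#' @rdname GMMModel-class
#' @export
setMethod("componentSigmas", "GMMModel", function(x) x@sigmas)

#' @rdname GMMModel-class
#' @export
setMethod("bicTrace", "GMMModel", function(x) x@bicTrace)

#' @rdname MembershipFunctionSet-class
#' @export
setMethod("retainedComponents", "MembershipFunctionSet", function(x) x@retained)

#' @rdname ExpandedMatrix-class
#' @export
setMethod("featureProvenance", "ExpandedMatrix", function(x) x@provenance)

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d cells x %d markers (%s space)\n",
              nrow(object@values), ncol(object@values),
              if (object@transformed) "arcsinh" else "raw"))
  cat("markers:", paste(utils::head(markerNames(object), 8L), collapse = ", "),
      if (ncol(object@values) > 8L) "..." else "", "\n")
  if (length(object@cellLabels)) {
    cat(sprintf("labels: %d populations\n", length(unique(object@cellLabels))))
  }
  if (object@nDropped > 0L) {
    cat(sprintf("rows dropped on load (non-finite): %d\n", object@nDropped))
  }
})

setMethod("show", "GMMModel", function(object) {
  cat(sprintf("GMMModel for '%s': K = %d (n = %d)\n",
              object@markerName, object@K, object@nObs))
  print(round(data.frame(weight = object@weights, mean = object@means,
                         sigma = object@sigmas), 4L))
  if (length(object@bicTrace)) {
    cat("BIC trace:", paste(sprintf("K=%s: %.1f", names(object@bicTrace),
                                    object@bicTrace), collapse = "; "), "\n")
  }
})

setMethod("show", "ProbabilityLines", function(object) {
  cat(sprintf("ProbabilityLines for '%s': %d components on a %d-point grid [%.3g, %.3g]\n",
              object@markerName, nrow(object@P), length(object@grid),
              object@grid[1L], object@grid[length(object@grid)]))
})

setMethod("show", "ArtifactReport", function(object) {
  cat(sprintf("ArtifactReport (K = %d):\n", object@K))
  cat("  inactive:  ", if (length(object@inactive)) paste(object@inactive, collapse = ", ") else "none", "\n")
  cat("  multipeak: ", if (length(object@multipeak)) paste(object@multipeak, collapse = ", ") else "none", "\n")
  cat("  off-peak:  ", if (length(object@offPeak)) paste(object@offPeak, collapse = ", ") else "none", "\n")
  cat(sprintf("  order violations: %d\n", length(object@orderViolations)))
})

setMethod("show", "MembershipFunctionSet", function(object) {
  cat(sprintf("MembershipFunctionSet for '%s': %d retained components (original indices: %s)\n",
              object@markerName, nrow(object@curves),
              paste(object@retained, collapse = ", ")))
})

setMethod("show", "ExpandedMatrix", function(object) {
  cat(sprintf("ExpandedMatrix: %d cells x %d expanded features from %d markers\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@provenance$marker))))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d cells, %d markers, %d populations (seed %d)\n",
              object@nCells, object@nMarkers, nrow(object@populations),
              object@seed))
  print(object@populations)
})

setMethod("show", "ExpansionConfig", function(object) {
  cat(sprintf(paste0("ExpansionConfig: cofactor=%g, kMax=%d, sigmaMin=%g, ",
                     "nInit=%d, gridSize=%d, seed=%d, evaluation=%s\n"),
              object@cofactor, object@kMax, object@sigmaMin, object@nInit,
              object@gridSize, object@seed, object@evaluationSpace))
})

#' Construct an ExpansionConfig
#'
#' @param cofactor arcsinh cofactor (default 5).
#' @param kMax candidate-component ceiling (default 15).
#' @param sigmaMin sigma floor in arcsinh units (default 1e-3).
#' @param nInit EM restarts per candidate K (default 5).
#' @param gridSize posterior grid resolution (default 1024, minimum 64).
#' @param seed user seed for all derived RNG streams.
#' @param markerSubset optional character vector restricting the markers.
#' @param evaluationSpace space in which validity indices are computed:
#'   "clustered-space" (default) or "regular-space".
#' @return an [ExpansionConfig-class]
#' @export
expansionConfig <- function(cofactor = 5, kMax = 15L, sigmaMin = 1e-3,
                            nInit = 5L, gridSize = 1024L, seed = 1L,
                            markerSubset = NULL,
                            evaluationSpace = c("clustered-space", "regular-space")) {
  new("ExpansionConfig", cofactor = cofactor, kMax = as.integer(kMax),
      sigmaMin = sigmaMin, nInit = as.integer(nInit),
      gridSize = as.integer(gridSize), seed = as.integer(seed),
      markerSubset = markerSubset,
      evaluationSpace = match.arg(evaluationSpace))
}
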