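#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MarkerMatrix: cells-by-markers intensity table
#'
#' Container for single-cell cytometry intensities with cells as rows and
#' markers as columns, optionally carrying per-cell population labels and
#' batch identifiers.  The \code{transformed} flag records whether values
#' are raw intensities or arcsinh-transformed; \code{nDropped} counts rows
#' removed at load time because they contained non-finite entries.
#'
#' @slot values numeric matrix, \code{n_cells x n_markers}; column names are
#'   the marker names.
#' @slot cellLabels character vector of population labels (length
#'   \code{n_cells}) or empty.
#' @slot batchIds character vector of batch identifiers or empty.
#' @slot transformed logical scalar; \code{TRUE} once arcsinh-transformed.
#' @slot nDropped integer; rows dropped for non-finite values on load.
#'
#' @seealso [markerMatrix()], [readMarkerMatrix()], [arcsinhTransform()]
#' @export
setClass("MarkerMatrix",
  representation(
    values = "matrix",
    cellLabels = "character",
    batchIds = "character",
    transformed = "logical",
    nDropped = "integer"
  ),
  prototype(
    cellLabels = character(0),
    batchIds = character(0),
    transformed = FALSE,
    nDropped = 0L
  )
)

setValidity("MarkerMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) == 0L || ncol(v) == 0L) msgs <- c(msgs, "matrix is empty")
  nm <- colnames(v)
  if (is.null(nm) || any(!nzchar(nm))) {
    msgs <- c(msgs, "all columns must carry a marker name")
  } else if (anyDuplicated(nm)) {
    msgs <- c(msgs, sprintf("duplicate marker names: %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (is.numeric(v) && any(!is.finite(v))) {
    msgs <- c(msgs, "values contain non-finite entries")
  }
  if (length(object@cellLabels) > 0L && length(object@cellLabels) != nrow(v)) {
    msgs <- c(msgs, "cellLabels length must equal the number of cells")
  }
  if (length(object@batchIds) > 0L && length(object@batchIds) != nrow(v)) {
    msgs <- c(msgs, "batchIds length must equal the number of cells")
  }
  if (length(object@transformed) != 1L || is.na(object@transformed)) {
    msgs <- c(msgs, "transformed must be TRUE or FALSE")
  }
  if (length(msgs)) msgs else TRUE
})

#' Univariate Gaussian mixture fitted to one marker
#'
#' Holds the parameters of a per-marker mixture of \code{K} normal
#' components, relabeled so that means are ascending (ties broken by
#' ascending sigma, then ascending weight).  \code{bicTrace} stores the BIC
#' value obtained for every candidate component count so that the selected
#' \code{K} is auditable; \code{sigmaMin} is the floor imposed on component
#' standard deviations during fitting.  \code{componentIndex} tracks the
#' original component indices so that provenance survives removal of
#' inactive components.
#'
#' @slot markerName character scalar.
#' @slot K integer; number of components.
#' @slot weights,means,sigmas numeric vectors of length \code{K}.
#' @slot nObs integer; number of observations the model was fitted on.
#' @slot bicTrace named numeric; BIC per candidate K (names are the K values).
#' @slot logLik numeric; log-likelihood of the fitted model.
#' @slot seed integer; user seed the restart seeds were derived from.
#' @slot sigmaMin numeric; lower bound applied to sigmas.
#' @slot dataRange numeric length-2; observed [min, max] of the fitted data.
#' @slot componentIndex integer; original component indices (1..K at fit time).
#' @slot fitInfo list of fitting diagnostics (EM iterations, convergence,
#'   largest observed log-likelihood decrease).
#'
#' @seealso [fitMarkerGMM()], [posteriorLines()]
#' @export
setClass("GMMModel",
  representation(
    markerName = "character",
    K = "integer",
    weights = "numeric",
    means = "numeric",
    sigmas = "numeric",
    nObs = "integer",
    bicTrace = "numeric",
    logLik = "numeric",
    seed = "integer",
    sigmaMin = "numeric",
    dataRange = "numeric",
    componentIndex = "integer",
    fitInfo = "list"
  ),
  prototype(
    markerName = "marker", nObs = 0L, bicTrace = numeric(0),
    logLik = NA_real_, seed = 0L, sigmaMin = 1e-3, fitInfo = list()
  )
)

setValidity("GMMModel", function(object) {
  K <- object@K
  msgs <- character(0)
  if (length(K) != 1L || K < 1L) msgs <- c(msgs, "K must be a positive integer")
  for (s in c("weights", "means", "sigmas")) {
    if (length(slot(object, s)) != K) {
      msgs <- c(msgs, sprintf("%s must have length K = %d", s, K))
    }
  }
  if (length(msgs)) return(msgs)
  if (abs(sum(object@weights) - 1) > 1e-9) {
    msgs <- c(msgs, "component weights must sum to 1 (tolerance 1e-9)")
  }
  if (any(object@weights <= 0)) msgs <- c(msgs, "weights must be in (0, 1]")
  if (is.unsorted(object@means)) msgs <- c(msgs, "means must be ascending")
  if (any(object@sigmas < object@sigmaMin - 1e-12)) {
    msgs <- c(msgs, "all sigmas must be >= sigmaMin")
  }
  if (length(object@bicTrace) > 0L) {
    kStar <- as.integer(names(object@bicTrace)[which.min(object@bicTrace)])
    if (!identical(kStar, K)) {
      msgs <- c(msgs, "K must minimize bicTrace")
    }
  }
  if (length(object@dataRange) != 2L || any(!is.finite(object@dataRange)) ||
      diff(object@dataRange) < 0) {
    msgs <- c(msgs, "dataRange must be a finite [min, max] pair")
  }
  if (length(object@componentIndex) != K) {
    msgs <- c(msgs, "componentIndex must have length K")
  }
  if (length(msgs)) msgs else TRUE
})

#' Posterior ("conditional probability") curves of one marker's mixture
#'
#' A dense grid over a marker's observed range together with the K posterior
#' curves P(component | x).  Every grid column sums to 1.
#'
#' @slot markerName character scalar.
#' @slot grid ascending numeric vector of length G.
#' @slot P K x G numeric matrix of posteriors.
#' @slot model the source [GMMModel-class].
#'
#' @seealso [posteriorLines()], [detectArtifacts()], [correctLines()]
#' @export
setClass("ProbabilityLines",
  representation(
    markerName = "character",
    grid = "numeric",
    P = "matrix",
    model = "GMMModel"
  )
)

setValidity("ProbabilityLines", function(object) {
  msgs <- character(0)
  G <- length(object@grid)
  if (G < 2L || is.unsorted(object@grid, strictly = TRUE)) {
    msgs <- c(msgs, "grid must be strictly ascending with length >= 2")
  }
  if (nrow(object@P) != object@model@K || ncol(object@P) != G) {
    msgs <- c(msgs, "P must be K x G")
    return(msgs)
  }
  if (any(object@P < -1e-12) || any(object@P > 1 + 1e-12)) {
    msgs <- c(msgs, "posteriors must lie in [0, 1]")
  }
  cs <- colSums(object@P)
  if (any(abs(cs - 1) > 1e-9)) {
    msgs <- c(msgs, "every grid column of P must sum to 1 (tolerance 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Artifact report for a set of posterior curves
#'
#' Classifies the components of a fitted mixture by the artifacts their
#' posterior curves exhibit: components that are never dominant anywhere on
#' the grid (\code{inactive}), curves with more than one tolerated local
#' maximum (\code{multipeak}), dominance runs that disagree with the
#' ascending-mean component order (\code{orderViolations}), and components
#' whose posterior peak falls farther than 3 sigma from the component mean
#' (\code{offPeak}).
#'
#' @slot inactive integer indices of never-dominant components.
#' @slot multipeak integer indices of multi-peaked curves.
#' @slot orderViolations list of \code{list(component=, region=c(lo, hi))}.
#' @slot offPeak integer indices of components peaking far from their mean.
#' @slot K integer; component count of the source model.
#'
#' @seealso [detectArtifacts()], [removeInactive()]
#' @export
setClass("ArtifactReport",
  representation(
    inactive = "integer",
    multipeak = "integer",
    orderViolations = "list",
    offPeak = "integer",
    K = "integer"
  ),
  prototype(inactive = integer(0), multipeak = integer(0),
            orderViolations = list(), offPeak = integer(0))
)

setValidity("ArtifactReport", function(object) {
  idx <- c(object@inactive, object@multipeak, object@offPeak,
           vapply(object@orderViolations, function(v) v$component, 1L))
  if (length(idx) && (any(idx < 1L) || any(idx > object@K))) {
    return("component indices must lie in 1..K")
  }
  TRUE
})

#' Corrected membership functions of one marker
#'
#' The corrected, single-peaked curves of the retained components of one
#' marker's mixture: the callable definition of that marker's expanded
#' features.  The first curve equals 1 at the grid minimum and the last
#' curve equals 1 at the grid maximum; all other curve endpoints are 0.
#' Each retained component dominates on one contiguous grid interval and
#' these intervals follow ascending component means.
#'
#' @slot markerName character scalar.
#' @slot grid shared ascending grid (length G).
#' @slot retained integer; original component indices, ascending-mean order.
#' @slot curves R x G numeric matrix of membership values in [0, 1].
#' @slot anchors list (length R) of data.frames with columns \code{x},
#'   \code{y}: the control points each curve was re-modeled through.
#' @slot model the renormalized [GMMModel-class] after inactive removal.
#'
#' @seealso [correctLines()], [evaluateMembership()], [expandMatrix()]
#' @export
setClass("MembershipFunctionSet",
  representation(
    markerName = "character",
    grid = "numeric",
    retained = "integer",
    curves = "matrix",
    anchors = "list",
    model = "GMMModel"
  )
)

setValidity("MembershipFunctionSet", function(object) {
  msgs <- character(0)
  R <- nrow(object@curves)
  G <- length(object@grid)
  if (ncol(object@curves) != G) msgs <- c(msgs, "curves must be R x G")
  if (length(object@retained) != R) {
    msgs <- c(msgs, "retained must have one index per curve")
  }
  if (any(object@curves < -1e-9) || any(object@curves > 1 + 1e-9)) {
    msgs <- c(msgs, "membership values must lie in [0, 1]")
  }
  if (length(msgs)) return(msgs)
  for (r in seq_len(R)) {
    left <- if (r == 1L) 1 else 0
    right <- if (r == R) 1 else 0
    if (abs(object@curves[r, 1L] - left) > 1e-6 ||
        abs(object@curves[r, G] - right) > 1e-6) {
      msgs <- c(msgs, sprintf("curve %d violates its boundary values", r))
    }
    if (countPeaks(object@curves[r, ], tol = 1e-4) > 1L) {
      msgs <- c(msgs, sprintf("curve %d has more than one local maximum", r))
    }
  }
  runs <- rle(apply(object@curves, 2L, which.max))
  if (length(runs$values) != R || is.unsorted(runs$values, strictly = TRUE)) {
    msgs <- c(msgs, "dominance runs must be contiguous and mean-ordered")
  }
  if (length(msgs)) msgs else TRUE
})

#' Expanded feature matrix
#'
#' The cells-by-features projection of a [MarkerMatrix-class] through every
#' marker's membership functions.  Columns are named
#' \code{"<marker>__c<j>"} with \code{j} the retained-component rank, grouped
#' by marker in input order, and the \code{provenance} table maps each column
#' back to its marker and original mixture component.
#'
#' @slot values numeric matrix in [0, 1], cells x total retained components.
#' @slot provenance data.frame with columns \code{column}, \code{marker},
#'   \code{component}, \code{mean}, \code{sigma}, \code{weight}.
#' @slot cellLabels carried through from the input (may be empty).
#'
#' @seealso [expandMatrix()], [fitExpandPipeline()]
#' @export
setClass("ExpandedMatrix",
  representation(
    values = "matrix",
    provenance = "data.frame",
    cellLabels = "character"
  ),
  prototype(cellLabels = character(0))
)

setValidity("ExpandedMatrix", function(object) {
  msgs <- character(0)
  if (any(object@values < -1e-9) || any(object@values > 1 + 1e-9)) {
    msgs <- c(msgs, "expanded values must lie in [0, 1]")
  }
  if (nrow(object@provenance) != ncol(object@values)) {
    msgs <- c(msgs, "provenance must describe every column")
  } else if (!identical(object@provenance$column, colnames(object@values))) {
    msgs <- c(msgs, "provenance rows must match column names in order")
  }
  if (length(object@cellLabels) > 0L &&
      length(object@cellLabels) != nrow(object@values)) {
    msgs <- c(msgs, "cellLabels length must equal the number of cells")
  }
  if (length(msgs)) msgs else TRUE
})

#' Specification of a labeled synthetic cytometry dataset
#'
#' Defines populations by their abundances and by the mixture component each
#' population draws from on every marker.  The implied per-marker component
#' weights are the abundance totals of the populations assigned to each
#' component, so the generative model lies exactly within the per-marker
#' Gaussian-mixture family the method assumes.
#'
#' @slot nMarkers,nCells,seed integers.
#' @slot populations data.frame with columns \code{name}, \code{abundance}.
#' @slot assignments integer matrix, populations x markers; entry (p, j) is
#'   the component of marker j that population p draws from.
#' @slot markerModels list (length nMarkers) of \code{list(means=, sigmas=)}.
#' @slot definingMarker integer; marker singling out the rare population
#'   (0 when not applicable).
#' @slot rarePopulation character; name of the rare population ("" if none).
#'
#' @seealso [syntheticSpec()], [benchmarkSpec()], [simulateCytof()]
#' @export
setClass("SyntheticSpec",
  representation(
    nMarkers = "integer",
    nCells = "integer",
    seed = "integer",
    populations = "data.frame",
    assignments = "matrix",
    markerModels = "list",
    definingMarker = "integer",
    rarePopulation = "character"
  ),
  prototype(definingMarker = 0L, rarePopulation = "")
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  ab <- object@populations$abundance
  if (abs(sum(ab) - 1) > 1e-9) msgs <- c(msgs, "abundances must sum to 1")
  if (any(ab <= 0)) msgs <- c(msgs, "abundances must be positive")
  if (nrow(object@assignments) != nrow(object@populations) ||
      ncol(object@assignments) != object@nMarkers) {
    msgs <- c(msgs, "assignments must be populations x markers")
    return(msgs)
  }
  if (length(object@markerModels) != object@nMarkers) {
    msgs <- c(msgs, "markerModels must have one entry per marker")
    return(msgs)
  }
  for (j in seq_len(object@nMarkers)) {
    mm <- object@markerModels[[j]]
    nc <- length(mm$means)
    a <- object@assignments[, j]
    if (any(a < 1L) || any(a > nc) || any(a != as.integer(a))) {
      msgs <- c(msgs, sprintf("marker %d: invalid component assignment", j))
    }
    if (length(mm$sigmas) != nc || any(mm$sigmas <= 0)) {
      msgs <- c(msgs, sprintf("marker %d: sigmas must be positive, one per component", j))
    }
  }
  if (object@nCells < 1L) msgs <- c(msgs, "nCells must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the expansion pipeline
#'
#' Bundles the tunable parameters of the fit-and-expand pipeline: the
#' arcsinh cofactor, the candidate-component ceiling \code{kMax}, the sigma
#' floor, the number of EM restarts, the posterior grid size, the user seed,
#' an optional marker subset, and the space in which clustering evaluations
#' are computed.
#'
#' @slot cofactor positive numeric; arcsinh cofactor (default 5).
#' @slot kMax integer; largest candidate component count (default 15).
#' @slot sigmaMin positive numeric; sigma floor in arcsinh units (default 1e-3).
#' @slot nInit integer; EM restarts per candidate K (default 5).
#' @slot gridSize integer >= 64; posterior grid resolution (default 1024).
#' @slot seed integer user seed.
#' @slot markerSubset optional character vector of markers to process.
#' @slot evaluationSpace one of "clustered-space", "regular-space".
#'
#' @seealso [expansionConfig()], [fitExpandPipeline()]
#' @export
setClass("ExpansionConfig",
  representation(
    cofactor = "numeric",
    kMax = "integer",
    sigmaMin = "numeric",
    nInit = "integer",
    gridSize = "integer",
    seed = "integer",
    markerSubset = "characterOrNULL",
    evaluationSpace = "character"
  ),
  prototype(cofactor = 5, kMax = 15L, sigmaMin = 1e-3, nInit = 5L,
            gridSize = 1024L, seed = 1L, markerSubset = NULL,
            evaluationSpace = "clustered-space")
)

setValidity("ExpansionConfig", function(object) {
  msgs <- character(0)
  if (object@cofactor <= 0) msgs <- c(msgs, "cofactor must be positive")
  if (object@kMax < 1L) msgs <- c(msgs, "kMax must be >= 1")
  if (object@sigmaMin <= 0) msgs <- c(msgs, "sigmaMin must be positive")
  if (object@nInit < 1L) msgs <- c(msgs, "nInit must be >= 1")
  if (object@gridSize < 64L) msgs <- c(msgs, "gridSize must be >= 64")
  if (!object@evaluationSpace %in% c("clustered-space", "regular-space")) {
    msgs <- c(msgs, "evaluationSpace must be 'clustered-space' or 'regular-space'")
  }
  if (length(msgs)) msgs else TRUE
})
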