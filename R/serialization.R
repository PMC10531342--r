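# JSON round trips for fitted objects.  All numerics are written with 17
# significant digits, so write/read round trips are bitwise lossless.

#' Write a fitted mixture model to JSON
#'
#' @param model a [GMMModel-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeGMMModel <- function(model, path) {
  stopifnot(is(model, "GMMModel"))
  obj <- list(marker = model@markerName, K = model@K,
              weights = model@weights, means = model@means,
              sigmas = model@sigmas, n_obs = model@nObs,
              sigma_min = model@sigmaMin, seed = model@seed,
              log_lik = model@logLik,
              data_range = model@dataRange,
              component_index = model@componentIndex,
              bic_trace = as.list(stats::setNames(as.numeric(model@bicTrace),
                                                  names(model@bicTrace))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a mixture model from JSON
#'
#' @param path file written by [writeGMMModel()]
#' @return a [GMMModel-class]
#' @export
readGMMModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bt <- unlist(obj$bic_trace)
  new("GMMModel", markerName = obj$marker, K = as.integer(obj$K),
      weights = as.numeric(obj$weights), means = as.numeric(obj$means),
      sigmas = as.numeric(obj$sigmas), nObs = as.integer(obj$n_obs),
      bicTrace = if (length(bt)) bt else numeric(0),
      logLik = if (is.null(obj$log_lik)) NA_real_ else as.numeric(obj$log_lik),
      seed = as.integer(obj$seed), sigmaMin = as.numeric(obj$sigma_min),
      dataRange = as.numeric(obj$data_range),
      componentIndex = as.integer(obj$component_index), fitInfo = list())
}

#' Write a membership-function set to JSON
#'
#' Serializes the grid, the corrected curves, the anchors and the
#' renormalized model.
#'
#' @param mfs a [MembershipFunctionSet-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeMembershipFunctions <- function(mfs, path) {
  stopifnot(is(mfs, "MembershipFunctionSet"))
  mdl <- mfs@model
  obj <- list(marker = mfs@markerName, grid = mfs@grid,
              retained = mfs@retained,
              curves = lapply(seq_len(nrow(mfs@curves)),
                              function(r) mfs@curves[r, ]),
              anchors = lapply(mfs@anchors, function(a) list(x = a$x, y = a$y)),
              model = list(weights = mdl@weights, means = mdl@means,
                           sigmas = mdl@sigmas, sigma_min = mdl@sigmaMin,
                           data_range = mdl@dataRange, n_obs = mdl@nObs,
                           seed = mdl@seed,
                           component_index = mdl@componentIndex))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a membership-function set from JSON
#'
#' @param path file written by [writeMembershipFunctions()]
#' @return a [MembershipFunctionSet-class]
#' @export
readMembershipFunctions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  md <- obj$model
  model <- new("GMMModel", markerName = obj$marker,
               K = length(md$means), weights = as.numeric(md$weights),
               means = as.numeric(md$means), sigmas = as.numeric(md$sigmas),
               nObs = as.integer(md$n_obs), bicTrace = numeric(0),
               logLik = NA_real_, seed = as.integer(md$seed),
               sigmaMin = as.numeric(md$sigma_min),
               dataRange = as.numeric(md$data_range),
               componentIndex = as.integer(md$component_index),
               fitInfo = list())
  curves <- obj$curves
  if (is.list(curves)) curves <- do.call(rbind, lapply(curves, as.numeric))
  curves <- matrix(as.numeric(curves), nrow = length(obj$retained))
  anchors <- if (is.data.frame(obj$anchors)) {
    lapply(seq_len(nrow(obj$anchors)), function(i) {
      data.frame(x = unlist(obj$anchors$x[i]), y = unlist(obj$anchors$y[i]))
    })
  } else {
    lapply(obj$anchors, function(a) data.frame(x = unlist(a$x), y = unlist(a$y)))
  }
  new("MembershipFunctionSet", markerName = obj$marker,
      grid = as.numeric(obj$grid), retained = as.integer(obj$retained),
      curves = curves, anchors = anchors, model = model)
}

#' Write an expanded matrix as delimited text plus a JSON sidecar
#'
#' The matrix is written with the provenance column names as header; the
#' sidecar maps every column to its (marker, component, mean, sigma,
#' weight).
#'
#' @param em an [ExpandedMatrix-class]
#' @param path output file for the matrix
#' @param sidecar path of the JSON sidecar (default \code{<path>.json});
#'   \code{NULL} skips it
#' @param sep field separator
#' @return \code{path}, invisibly
#' @export
writeExpandedMatrix <- function(em, path, sidecar = paste0(path, ".json"),
                                sep = ",") {
  stopifnot(is(em, "ExpandedMatrix"))
  v <- em@values
  cols <- lapply(seq_len(ncol(v)), function(j) sprintf("%.17g", v[, j]))
  header <- colnames(v)
  if (length(em@cellLabels)) {
    cols <- c(cols, list(em@cellLabels))
    header <- c(header, "population")
  }
  writeLines(c(paste(header, collapse = sep),
               do.call(paste, c(cols, sep = sep))), path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(em@provenance, sidecar, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Write / read a synthetic-data specification as JSON
#'
#' @param spec a [SyntheticSpec-class]
#' @param path JSON file
#' @return \code{path} (write) or the [SyntheticSpec-class] (read)
#' @export
writeSyntheticSpec <- function(spec, path) {
  stopifnot(is(spec, "SyntheticSpec"))
  obj <- list(n_markers = spec@nMarkers, n_cells = spec@nCells,
              seed = spec@seed,
              populations = spec@populations,
              assignments = lapply(seq_len(nrow(spec@assignments)),
                                   function(p) spec@assignments[p, ]),
              marker_names = names(spec@markerModels),
              marker_models = lapply(spec@markerModels, function(mm) {
                list(means = mm$means, sigmas = mm$sigmas)
              }),
              defining_marker = spec@definingMarker,
              rare_population = spec@rarePopulation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignments <- obj$assignments
  if (is.list(assignments)) {
    assignments <- do.call(rbind, lapply(assignments, as.integer))
  }
  dimnames(assignments) <- NULL
  storage.mode(assignments) <- "integer"
  mm <- lapply(seq_len(obj$n_markers), function(j) {
    list(means = as.numeric(obj$marker_models[[j]]$means),
         sigmas = as.numeric(obj$marker_models[[j]]$sigmas))
  })
  syntheticSpec(populations = as.data.frame(obj$populations),
                assignments = assignments, markerModels = mm,
                nCells = obj$n_cells, seed = obj$seed,
                markerNames = obj$marker_names,
                definingMarker = obj$defining_marker,
                rarePopulation = obj$rare_population)
}
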