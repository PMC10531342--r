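validateClustering <- function(X, labels) {
  X <- as.matrix(X)
  if (length(labels) != nrow(X)) {
    stopf("labels length (%d) must equal the number of rows (%d)",
          length(labels), nrow(X))
  }
  f <- factor(labels)
  if (nlevels(f) < 2L) {
    stopf("at least 2 distinct clusters are required for the index")
  }
  list(X = X, f = f, k = nlevels(f), n = nrow(X))
}

#' Calinski-Harabasz index
#'
#' \code{CH = [tr(B)/(k - 1)] / [tr(W)/(n - k)]} where B and W are the
#' between- and within-cluster sum-of-squares about the centroids.  Higher
#' values indicate tighter, better-separated clusters.  A zero
#' within-cluster dispersion with \code{k >= 2} yields \code{Inf}.
#'
#' @param X numeric matrix, observations in rows
#' @param labels cluster assignment (any type coercible to factor), one per
#'   row; at least two nonempty clusters
#' @return the index value
#' @examples
#' X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' calinskiHarabasz(X, c("A", "A", "B", "B"))  # 200
#' @export
calinskiHarabasz <- function(X, labels) {
  v <- validateClustering(X, labels)
  grand <- colMeans(v$X)
  trW <- 0
  trB <- 0
  for (lev in levels(v$f)) {
    idx <- v$f == lev
    xc <- v$X[idx, , drop = FALSE]
    cen <- colMeans(xc)
    trW <- trW + sum(sweep(xc, 2L, cen)^2)
    trB <- trB + sum(idx) * sum((cen - grand)^2)
  }
  if (trW == 0) return(Inf)
  (trB / (v$k - 1)) / (trW / (v$n - v$k))
}

#' Davies-Bouldin index
#'
#' \code{DB = (1/k) sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j)} with
#' cluster scatter \code{s_i} the mean Euclidean distance to the centroid.
#' Lower values indicate better-separated clusters.  Coincident centroids
#' of distinct clusters yield \code{Inf}.
#'
#' @inheritParams calinskiHarabasz
#' @return the index value
#' @examples
#' X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' daviesBouldin(X, c("A", "A", "B", "B"))  # 0.1
#' @export
daviesBouldin <- function(X, labels) {
  v <- validateClustering(X, labels)
  cent <- matrix(0, v$k, ncol(v$X))
  scat <- numeric(v$k)
  for (i in seq_len(v$k)) {
    xc <- v$X[v$f == levels(v$f)[i], , drop = FALSE]
    cent[i, ] <- colMeans(xc)
    scat[i] <- mean(sqrt(rowSums(sweep(xc, 2L, cent[i, ])^2)))
  }
  total <- 0
  for (i in seq_len(v$k)) {
    best <- -Inf
    for (j in seq_len(v$k)) {
      if (j == i) next
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      r <- if (d == 0) Inf else (scat[i] + scat[j]) / d
      if (r > best) best <- r
    }
    total <- total + best
  }
  total / v$k
}

#' Built-in k-means baseline clustering
#'
#' Seeded k-means used as the package's stand-in for external clusterers
#' when comparing the regular and expanded spaces (external tools enter
#' through label files instead).
#'
#' @param X numeric matrix, observations in rows
#' @param k number of clusters
#' @param seed RNG seed
#' @param nstart,iterMax passed to [stats::kmeans()]
#' @return integer cluster labels, one per row
#' @export
kmeansBaseline <- function(X, k, seed = 1L, nstart = 10L, iterMax = 100L) {
  withr::with_seed(as.integer(seed), {
    # near-binary membership features trigger benign Quick-TRANSfer
    # warnings; the optimum matches Lloyd/MacQueen
    suppressWarnings(stats::kmeans(as.matrix(X), centers = k,
                                   nstart = nstart,
                                   iter.max = iterMax)$cluster)
  })
}

#' Compare clustering quality in the regular and expanded spaces
#'
#' Computes the Calinski-Harabasz and Davies-Bouldin indices for each
#' supplied labeling in both feature spaces and returns them in a tabular
#' layout (one row per labeling and space).
#'
#' @param regular the regular-space matrix (a [MarkerMatrix-class] or
#'   numeric matrix)
#' @param expanded the expanded-space matrix (an [ExpandedMatrix-class] or
#'   numeric matrix)
#' @param labelings named list of label vectors, one name ("algorithm tag")
#'   per labeling; a single unnamed vector is also accepted
#' @param evaluationSpace \code{"clustered-space"} (default) computes each
#'   row's indices on the matrix of the space being evaluated;
#'   \code{"regular-space"} computes all indices on the regular matrix, so
#'   labelings from different spaces are compared on common ground
#' @return a data.frame with columns \code{algorithm}, \code{space},
#'   \code{n_clusters}, \code{chi}, \code{dbi}
#' @export
compareSpaces <- function(regular, expanded, labelings,
                          evaluationSpace = c("clustered-space",
                                              "regular-space")) {
  evaluationSpace <- match.arg(evaluationSpace)
  Xr <- if (is(regular, "MarkerMatrix")) regular@values else as.matrix(regular)
  Xe <- if (is(expanded, "ExpandedMatrix")) expanded@values else as.matrix(expanded)
  if (nrow(Xr) != nrow(Xe)) {
    stopf("regular (%d rows) and expanded (%d rows) matrices must align",
          nrow(Xr), nrow(Xe))
  }
  if (!is.list(labelings)) labelings <- list(labels = labelings)
  if (is.null(names(labelings))) {
    names(labelings) <- paste0("labeling", seq_along(labelings))
  }
  rows <- list()
  for (tag in names(labelings)) {
    lab <- labelings[[tag]]
    if (length(lab) != nrow(Xr)) {
      stopf("labeling '%s' has %d entries for %d cells", tag, length(lab), nrow(Xr))
    }
    for (space in c("regular", "expanded")) {
      X <- if (space == "regular" || evaluationSpace == "regular-space") {
        Xr
      } else {
        Xe
      }
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = tag, space = space,
        n_clusters = length(unique(lab)),
        chi = calinskiHarabasz(X, lab),
        dbi = daviesBouldin(X, lab),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
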