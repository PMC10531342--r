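#' Posterior curves of a fitted marker mixture
#'
#' Evaluates the component posteriors
#' \code{P(k | x) = w_k phi(x; m_k, s_k) / sum_j w_j phi(x; m_j, s_j)} on a
#' dense equally spaced grid spanning the observed range of the fitted
#' data.  Computation is done in log space with log-sum-exp, so far tails
#' never produce 0/0.
#'
#' @param model a [GMMModel-class]
#' @param gridSize number of grid points (default 1024, minimum 64)
#' @param range optional [lo, hi] overriding the model's data range
#' @return a [ProbabilityLines-class]
#' @examples
#' mod <- gmmModel(c(0.5, 0.5), c(0, 4), c(1, 1))
#' pl <- posteriorLines(mod, gridSize = 256)
#' colSums(pl@P)[1:3]  # always 1
#' @export
posteriorLines <- function(model, gridSize = 1024L, range = NULL) {
  stopifnot(is(model, "GMMModel"))
  gridSize <- as.integer(gridSize)
  if (gridSize < 64L) stopf("gridSize must be >= 64")
  rg <- if (is.null(range)) model@dataRange else as.numeric(range)
  if (length(rg) != 2L || rg[2L] <= rg[1L]) stopf("invalid grid range")
  x <- seq(rg[1L], rg[2L], length.out = gridSize)
  K <- model@K
  lp <- matrix(0, K, gridSize)
  for (k in seq_len(K)) {
    lp[k, ] <- log(model@weights[k]) +
      stats::dnorm(x, model@means[k], model@sigmas[k], log = TRUE)
  }
  lse <- apply(lp, 2L, function(col) {
    m <- max(col)
    m + log(sum(exp(col - m)))
  })
  P <- exp(sweep(lp, 2L, lse, "-"))
  new("ProbabilityLines", markerName = model@markerName, grid = x,
      P = P, model = model)
}

#' Detect artifacts in posterior curves
#'
#' Classifies the three artifact families that arise when component
#' posteriors are used as features: \emph{inactive} components that are
#' never the columnwise argmax anywhere on the grid; \emph{multipeak}
#' curves with two or more tolerated local maxima (a broad component can
#' dominate both below and above a narrower one); and \emph{order
#' violations}, dominance runs whose sequence disagrees with the
#' ascending-mean component order.  A component is additionally flagged
#' \emph{off-peak} when its curve, restricted to \code{mean +/- 3 sigma},
#' never comes within \code{peakTolerance} of the curve's global maximum,
#' i.e. its peak is not located near the component mean.
#'
#' Dominance ties are broken toward the lower-mean component.
#'
#' @param lines a [ProbabilityLines-class]
#' @param peakTolerance dip depth below which neighbouring discrete maxima
#'   are merged (default 1e-4, ignoring floating-point ripples)
#' @return an [ArtifactReport-class]
#' @export
detectArtifacts <- function(lines, peakTolerance = 1e-4) {
  stopifnot(is(lines, "ProbabilityLines"))
  P <- lines@P
  grid <- lines@grid
  model <- lines@model
  K <- model@K
  am <- apply(P, 2L, which.max)
  runs <- rle(am)
  inactive <- setdiff(seq_len(K), unique(am))

  multipeak <- which(vapply(seq_len(K), function(k) {
    countPeaks(P[k, ], tol = peakTolerance) >= 2L
  }, TRUE))

  violations <- list()
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  maxSeen <- 0L
  for (i in seq_along(runs$values)) {
    comp <- runs$values[i]
    if (comp <= maxSeen) {
      violations[[length(violations) + 1L]] <-
        list(component = as.integer(comp),
             region = c(grid[starts[i]], grid[ends[i]]))
    }
    maxSeen <- max(maxSeen, comp)
  }

  offPeak <- which(vapply(seq_len(K), function(k) {
    near <- abs(grid - model@means[k]) <= 3 * model@sigmas[k]
    if (!any(near)) return(TRUE)
    max(P[k, near]) < max(P[k, ]) - peakTolerance
  }, TRUE))

  new("ArtifactReport", inactive = as.integer(inactive),
      multipeak = as.integer(multipeak), orderViolations = violations,
      offPeak = as.integer(offPeak), K = K)
}

#' Remove inactive components and renormalize
#'
#' Deletes the components an [ArtifactReport-class] marked inactive and
#' renormalizes the remaining weights to sum to 1; means and sigmas are not
#' re-fitted.  Original component indices are preserved in the
#' \code{componentIndex} slot.  The BIC trace is dropped because it
#' describes the pre-removal model selection.
#'
#' @param model the [GMMModel-class] the report was computed from
#' @param report the matching [ArtifactReport-class]
#' @return the reduced [GMMModel-class] (unchanged if nothing is inactive)
#' @export
removeInactive <- function(model, report) {
  stopifnot(is(model, "GMMModel"), is(report, "ArtifactReport"))
  if (report@K != model@K) {
    stopf("artifact report was produced from a model with K = %d, not %d",
          report@K, model@K)
  }
  if (length(report@inactive) == 0L) return(model)
  keep <- setdiff(seq_len(model@K), report@inactive)
  if (length(keep) == 0L) stopf("removal would leave zero components")
  new("GMMModel", markerName = model@markerName, K = length(keep),
      weights = model@weights[keep] / sum(model@weights[keep]),
      means = model@means[keep], sigmas = model@sigmas[keep],
      nObs = model@nObs, bicTrace = numeric(0), logLik = NA_real_,
      seed = model@seed, sigmaMin = model@sigmaMin,
      dataRange = model@dataRange,
      componentIndex = model@componentIndex[keep], fitInfo = model@fitInfo)
}

#' Correct posterior curves into membership functions
#'
#' Applies the four-step correction that turns posterior ("conditional
#' probability") curves into single-peaked membership functions: each
#' retained component keeps only the dominance run containing (or nearest
#' to) its mean; anchor points are sampled from the original posterior
#' within \code{mean +/- 3 sigma} of that run, always including the peak
#' summit and the grid points flanking the intersections with the adjacent
#' components' curves; the first curve is anchored at value 1 at the grid
#' minimum and the last at value 1 at the grid maximum, while every other
#' curve endpoint is forced to 0; curves are then re-modeled through the
#' anchors with monotone piecewise-cubic (pchip) interpolation, so no new
#' extrema and no values outside [0, 1] appear.
#'
#' Correction is selective: a set of curves that already satisfies every
#' membership invariant (single peaks, boundary values, contiguous
#' mean-ordered dominance, peaks near the means) is passed through
#' unchanged apart from exact snapping of the boundary values, which makes
#' the correction idempotent.
#'
#' Inactive components must have been removed first (see
#' [removeInactive()]); their presence is an error.
#'
#' @param lines a [ProbabilityLines-class] of the (reduced) model
#' @param peakTolerance tolerance for discrete peak detection (default 1e-4)
#' @param anchorsPerSide number of anchor points sampled on each side of a
#'   peak (default 11)
#' @return a [MembershipFunctionSet-class]
#' @examples
#' mod <- gmmModel(c(0.5, 0.5), c(0, 6), c(1, 1))
#' mfs <- correctLines(posteriorLines(mod, 256))
#' evaluateMembership(mfs, 3)  # both memberships about 0.5 at the midpoint
#' @export
correctLines <- function(lines, peakTolerance = 1e-4, anchorsPerSide = 11L) {
  stopifnot(is(lines, "ProbabilityLines"))
  model <- lines@model
  P <- lines@P
  grid <- lines@grid
  K <- model@K
  G <- length(grid)

  report <- detectArtifacts(lines, peakTolerance)
  if (length(report@inactive)) {
    stopf("inactive component(s) %s present; run removeInactive() first",
          paste(report@inactive, collapse = ", "))
  }

  if (K == 1L) {
    curves <- matrix(1, 1L, G)
    return(new("MembershipFunctionSet", markerName = model@markerName,
               grid = grid, retained = model@componentIndex, curves = curves,
               anchors = list(data.frame(x = grid[c(1L, G)], y = c(1, 1))),
               model = model))
  }

  am <- apply(P, 2L, which.max)
  runs <- rle(am)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  keptRegion <- function(r) {
    idx <- which(runs$values == r)
    if (length(idx) == 0L) {
      stopf("component %d has no dominance region; rerun detectArtifacts()", r)
    }
    if (length(idx) > 1L) {
      m <- model@means[r]
      contains <- vapply(idx, function(i) {
        grid[starts[i]] <= m && m <= grid[ends[i]]
      }, TRUE)
      idx <- if (any(contains)) idx[which(contains)[1L]] else {
        d <- vapply(idx, function(i) {
          min(abs(grid[c(starts[i], ends[i])] - m))
        }, 0)
        idx[which.min(d)]
      }
    }
    c(starts[idx], ends[idx])
  }

  compliant <- identical(runs$values, seq_len(K)) &&
    length(report@multipeak) == 0L && length(report@offPeak) == 0L &&
    all(abs(P[1L, 1L] - 1) <= 1e-6, abs(P[K, G] - 1) <= 1e-6,
        abs(P[-1L, 1L]) <= 1e-6, abs(P[-K, G]) <= 1e-6)

  if (compliant) {
    curves <- P
    curves[, 1L] <- c(1, rep(0, K - 1L))
    curves[, G] <- c(rep(0, K - 1L), 1)
    anchors <- lapply(seq_len(K), function(r) {
      reg <- keptRegion(r)
      gs <- reg[1L] - 1L + which.max(P[r, reg[1L]:reg[2L]])
      data.frame(x = grid[unique(c(1L, gs, G))],
                 y = curves[r, unique(c(1L, gs, G))])
    })
    return(new("MembershipFunctionSet", markerName = model@markerName,
               grid = grid, retained = model@componentIndex,
               curves = curves, anchors = anchors, model = model))
  }

  sampleIdx <- function(from, to, n) {
    if (to < from) return(integer(0))
    unique(round(seq(from, to, length.out = min(n, to - from + 1L))))
  }

  curves <- matrix(0, K, G)
  anchors <- vector("list", K)
  for (r in seq_len(K)) {
    reg <- keptRegion(r)
    gl <- reg[1L]; gr <- reg[2L]
    gs <- gl - 1L + which.max(P[r, gl:gr])
    m <- model@means[r]; s <- model@sigmas[r]
    lo3 <- max(gl, findInterval(m - 3 * s, grid) + 1L)
    hi3 <- min(gr, findInterval(m + 3 * s, grid))

    ii <- c(gs)
    if (r > 1L) {
      # left flank: anchors within the kept region plus the points flanking
      # the intersection with the lower neighbour's curve
      ii <- c(ii, sampleIdx(max(gl, min(lo3, gs)), gs, anchorsPerSide))
      ii <- c(ii, gl, max(gl - 1L, 1L))
    }
    if (r < K) {
      ii <- c(ii, sampleIdx(gs, min(gr, max(hi3, gs)), anchorsPerSide))
      ii <- c(ii, gr, min(gr + 1L, G))
    }
    ii <- sort(unique(c(1L, ii, G)))
    y <- P[r, ii]
    # boundary contract: first/last curves start/end at 1, the rest at 0
    y[ii == 1L] <- if (r == 1L) 1 else 0
    y[ii == G] <- if (r == K) 1 else 0
    # enforce a single peak: non-decreasing into the summit (or the forced
    # 1-boundary for the first/last curve), non-increasing after it
    peakPos <- if (r == 1L) 1L else if (r == K) length(ii) else which(ii == gs)[1L]
    if (peakPos > 1L) {
      head_ <- y[seq_len(peakPos)]
      y[seq_len(peakPos)] <- rev(cummin(rev(head_)))  # no value above the peak
      y[seq_len(peakPos)] <- cummax(y[seq_len(peakPos)])
    }
    if (peakPos < length(ii)) {
      tail_ <- y[peakPos:length(ii)]
      y[peakPos:length(ii)] <- cummin(tail_)
    }
    yy <- pracma::pchip(grid[ii], y, grid)
    yy <- pmin(pmax(yy, 0), 1)
    yy[1L] <- if (r == 1L) 1 else 0
    yy[G] <- if (r == K) 1 else 0
    curves[r, ] <- yy
    anchors[[r]] <- data.frame(x = grid[ii], y = y)
  }

  new("MembershipFunctionSet", markerName = model@markerName, grid = grid,
      retained = model@componentIndex, curves = curves, anchors = anchors,
      model = model)
}

#' Evaluate membership functions at marker values
#'
#' Linearly interpolates each corrected curve at \code{x}; values outside
#' the grid are clamped to the nearest grid endpoint.
#'
#' @param mfs a [MembershipFunctionSet-class]
#' @param x finite numeric vector of marker values
#' @return for scalar \code{x}, a named numeric vector with one membership
#'   per retained component; otherwise a \code{length(x) x R} matrix
#' @export
evaluateMembership <- function(mfs, x) {
  stopifnot(is(mfs, "MembershipFunctionSet"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stopf("x must be finite numeric")
  }
  R <- nrow(mfs@curves)
  out <- matrix(0, length(x), R)
  for (r in seq_len(R)) {
    out[, r] <- stats::approx(mfs@grid, mfs@curves[r, ], xout = x,
                              rule = 2L)$y
  }
  colnames(out) <- sprintf("c%d", seq_len(R))
  if (length(x) == 1L) out[1L, ] else out
}
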