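#' Fit a univariate Gaussian mixture to one marker
#'
#' Runs EM for every candidate component count \code{K = 1..kMax}, each with
#' \code{nInit} restarts, and selects K by the Bayesian Information
#' Criterion \code{BIC = -2 logL + p log(n)} with \code{p = 3K - 1} free
#' parameters.  Component standard deviations are floored at
#' \code{sigmaMin} throughout (the floor is applied at every M step and the
#' reported log-likelihood is evaluated at the floored parameters).  The
#' returned components are relabeled in ascending-mean order, ties broken by
#' ascending sigma then ascending weight, so relabeling is total and
#' deterministic.
#'
#' The first restart initializes means at the \code{(k - 0.5)/K} sample
#' quantiles with equal weights; the second places means equally spaced
#' over the observed range, which seeds components in sparse intermediate
#' regions that quantile spacing skips over (where rare intermediate
#' populations live); the remaining restarts draw means from the observed
#' values under seeds derived deterministically from
#' \code{(seed, markerIndex, K, restart)}, so a fit is fully reproducible
#' from the user seed alone.
#'
#' @param values finite numeric vector of marker intensities; at least
#'   \code{10 * kMax} observations are required.
#' @param kMax largest candidate component count (default 15, giving
#'   headroom over the 2-13 components typical of CyTOF markers).
#' @param sigmaMin positive sigma floor in the marker's units (default 1e-3).
#' @param nInit EM restarts per candidate K (default 5).
#' @param seed user seed from which all restart seeds are derived.
#' @param markerIndex index of the marker within its panel, used only for
#'   seed derivation (default 1).
#' @param markerName name stored in the model.
#' @param subsampleCap optional opt-in cap on the number of observations
#'   used for fitting (seeded subsample); \code{NULL} (default) fits on all
#'   observations.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8;
#'   looser tolerances can stop EM on the slow plateau that precedes the
#'   growth of a low-weight component).
#' @param maxIter EM iteration cap for the refinement stage (default 500).
#' @return a [GMMModel-class]
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0, 0.5), rnorm(300, 4, 0.5))
#' fit <- fitMarkerGMM(x, kMax = 3, seed = 1)
#' nComponents(fit)
#' @export
fitMarkerGMM <- function(values, kMax = 15L, sigmaMin = 1e-3, nInit = 5L,
                         seed = 1L, markerIndex = 1L, markerName = "marker",
                         subsampleCap = NULL, tol = 1e-8, maxIter = 500L) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stopf("values must be a finite numeric vector")
  }
  kMax <- as.integer(kMax)
  if (kMax < 1L) stopf("kMax must be >= 1")
  if (sigmaMin <= 0) stopf("sigmaMin must be positive")
  if (!is.null(subsampleCap) && length(values) > subsampleCap) {
    idx <- withr::with_seed(deriveSeed(seed, markerIndex, 0L, 0L),
                            sample.int(length(values), subsampleCap))
    values <- values[idx]
  }
  n <- length(values)
  if (n < 10L * kMax) {
    stopf("need at least 10*kMax = %d observations, got %d", 10L * kMax, n)
  }
  if (diff(range(values)) == 0) {
    stopf("degenerate input: all %d values identical (no mixture to fit)", n)
  }

  sdAll <- stats::sd(values)
  bic <- rep(NA_real_, kMax)
  fits <- vector("list", kMax)
  maxDecrease <- 0
  for (K in seq_len(kMax)) {
    if (K == 1L) {
      # closed-form single-Gaussian MLE
      mu <- mean(values)
      sg <- max(sqrt(stats::var(values) * (n - 1) / n), sigmaMin)
      ll <- gmm_loglik_cpp(values, 1, mu, sg)
      fits[[K]] <- list(weights = 1, means = mu, sigmas = sg, logLik = ll,
                        iterations = 0L, converged = TRUE)
    } else {
      # two-stage EM: every restart runs briefly at a loose tolerance, then
      # only the best restart is refined to full convergence
      stage1Tol <- max(tol, 1e-5)
      stage1Iter <- min(maxIter, 100L)
      best <- NULL
      for (init in seq_len(nInit)) {
        if (init == 1L) {
          mu0 <- stats::quantile(values, probs = (seq_len(K) - 0.5) / K,
                                 names = FALSE, type = 7)
        } else if (init == 2L) {
          rg <- range(values)
          mu0 <- rg[1L] + (seq_len(K) - 0.5) / K * diff(rg)
        } else {
          rs <- deriveSeed(seed, markerIndex, K, init)
          mu0 <- withr::with_seed(rs, sort(sample(values, K)))
        }
        sg0 <- rep(max(sdAll / K, sigmaMin), K)
        fit <- em_gmm_cpp(values, rep(1 / K, K), mu0, sg0,
                          sigmaMin, stage1Tol, stage1Iter)
        if (fit$maxDecrease > maxDecrease) maxDecrease <- fit$maxDecrease
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
      }
      fit <- em_gmm_cpp(values, best$weights, best$means, best$sigmas,
                        sigmaMin, tol, maxIter)
      if (fit$maxDecrease > maxDecrease) maxDecrease <- fit$maxDecrease
      fits[[K]] <- fit
    }
    p <- 3 * K - 1
    bic[K] <- -2 * fits[[K]]$logLik + p * log(n)
  }

  kStar <- which.min(bic)
  f <- fits[[kStar]]
  ord <- orderComponents(f$means, f$sigmas, f$weights)
  new("GMMModel",
      markerName = markerName, K = as.integer(kStar),
      weights = as.numeric(f$weights[ord]) / sum(f$weights),
      means = as.numeric(f$means[ord]), sigmas = as.numeric(f$sigmas[ord]),
      nObs = n, bicTrace = stats::setNames(bic, seq_len(kMax)),
      logLik = f$logLik, seed = as.integer(seed), sigmaMin = sigmaMin,
      dataRange = range(values), componentIndex = seq_len(kStar),
      fitInfo = list(maxLogLikDecrease = maxDecrease,
                     iterations = f$iterations,
                     converged = isTRUE(f$converged),
                     markerIndex = as.integer(markerIndex)))
}

#' Log-likelihood of data under a fitted mixture
#'
#' Computes \code{sum_i log(sum_k w_k phi(x_i; m_k, s_k))} with log-sum-exp
#' stabilization.
#'
#' @param model a [GMMModel-class]
#' @param values finite numeric vector
#' @return the log-likelihood (a single number)
#' @export
logLikGMM <- function(model, values) {
  stopifnot(is(model, "GMMModel"))
  if (!is.numeric(values) || any(!is.finite(values))) {
    stopf("values must be a finite numeric vector")
  }
  gmm_loglik_cpp(values, model@weights, model@means, model@sigmas)
}

#' Mixture density of a fitted model
#'
#' @param model a [GMMModel-class]
#' @param x numeric vector of evaluation points
#' @return the mixture density at each \code{x}
#' @export
densityGMM <- function(model, x) {
  stopifnot(is(model, "GMMModel"))
  d <- matrix(0, length(x), model@K)
  for (k in seq_len(model@K)) {
    d[, k] <- model@weights[k] * stats::dnorm(x, model@means[k], model@sigmas[k])
  }
  rowSums(d)
}
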