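# Independent oracles kept deliberately naive: direct formulas and double
# loops, no shared code with the implementation under test.

# posterior P(k | x) by the Bayes formula, densities via dnorm
posteriorOracle <- function(weights, means, sigmas, x) {
  K <- length(weights)
  sapply(seq_len(K), function(k) {
    num <- weights[k] * dnorm(x, means[k], sigmas[k])
    den <- 0
    for (j in seq_len(K)) den <- den + weights[j] * dnorm(x, means[j], sigmas[j])
    num / den
  })
}

# mixture log-likelihood by direct summation
logLikOracle <- function(weights, means, sigmas, x) {
  total <- 0
  for (xi in x) {
    s <- 0
    for (k in seq_along(weights)) {
      s <- s + weights[k] * dnorm(xi, means[k], sigmas[k])
    }
    total <- total + log(s)
  }
  total
}

# Calinski-Harabasz via explicit double loops
chiOracle <- function(X, labels) {
  X <- as.matrix(X)
  f <- factor(labels)
  n <- nrow(X); k <- nlevels(f)
  grand <- colMeans(X)
  trB <- 0; trW <- 0
  for (lev in levels(f)) {
    idx <- which(f == lev)
    cen <- colMeans(X[idx, , drop = FALSE])
    trB <- trB + length(idx) * sum((cen - grand)^2)
    for (i in idx) trW <- trW + sum((X[i, ] - cen)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

# Davies-Bouldin via explicit double loops
dbiOracle <- function(X, labels) {
  X <- as.matrix(X)
  f <- factor(labels)
  k <- nlevels(f)
  cent <- list(); scat <- numeric(k)
  for (i in seq_len(k)) {
    xi <- X[f == levels(f)[i], , drop = FALSE]
    cent[[i]] <- colMeans(xi)
    s <- 0
    for (r in seq_len(nrow(xi))) s <- s + sqrt(sum((xi[r, ] - cent[[i]])^2))
    scat[i] <- s / nrow(xi)
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      r <- (scat[i] + scat[j]) / d
      if (r > worst) worst <- r
    }
    total <- total + worst
  }
  total / k
}

# random valid mixture model parameters for property tests
randomMixture <- function(K, meanRange = c(-2, 8), sigmaRange = c(0.2, 1.5)) {
  w <- rgamma(K, 2, 1); w <- w / sum(w)
  list(weights = w,
       means = sort(runif(K, meanRange[1], meanRange[2])),
       sigmas = runif(K, sigmaRange[1], sigmaRange[2]))
}

# discrete peak count with a small dip tolerance, independent of the
# implementation's helper
countPeaksForTest <- function(y, tol = 1e-4) {
  r <- rle(y)
  v <- r$values
  starts <- cumsum(r$lengths) - r$lengths + 1
  peaks <- c()
  for (i in seq_along(v)) {
    if ((i == 1 || v[i - 1] < v[i]) && (i == length(v) || v[i + 1] < v[i])) {
      peaks <- c(peaks, starts[i])
    }
  }
  while (length(peaks) > 1) {
    dropped <- FALSE
    for (i in seq_len(length(peaks) - 1)) {
      valley <- min(y[peaks[i]:peaks[i + 1]])
      if (min(y[peaks[i]], y[peaks[i + 1]]) - valley <= tol) {
        peaks <- peaks[-(if (y[peaks[i]] < y[peaks[i + 1]]) i else i + 1)]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  length(peaks)
}
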