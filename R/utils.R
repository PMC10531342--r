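# Internal numerical helpers shared across modules.

# Count tolerated local maxima of a discrete curve.  Strict local maxima
# (boundaries count when higher than their inward neighbour) are pruned by
# persistence: two maxima separated by a dip shallower than `tol` (relative
# to the lower of the two) are merged into one.
countPeaks <- function(y, tol = 1e-4) {
  length(peakIndices(y, tol))
}

# Indices of the tolerated local maxima of `y` (see countPeaks).
peakIndices <- function(y, tol = 1e-4) {
  n <- length(y)
  if (n < 2L) return(1L)
  # collapse exact plateaus so comparisons are strict
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  cand <- integer(0)
  for (i in seq_len(m)) {
    leftLower <- i == 1L || v[i - 1L] < v[i]
    rightLower <- i == m || v[i + 1L] < v[i]
    if (leftLower && rightLower) cand <- c(cand, starts[i])
  }
  if (length(cand) <= 1L) return(cand)
  # persistence pruning: merge peaks split by dips shallower than tol
  repeat {
    if (length(cand) <= 1L) break
    merged <- FALSE
    for (i in seq_len(length(cand) - 1L)) {
      a <- cand[i]; b <- cand[i + 1L]
      valley <- min(y[a:b])
      if (min(y[a], y[b]) - valley <= tol) {
        drop <- if (y[a] < y[b]) i else i + 1L
        cand <- cand[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  cand
}

# log(sum(exp(x))) along rows of a matrix, guarding underflow
logRowSumExp <- function(lp) {
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

# Deterministic 32-bit seed derived from the user seed, a marker index,
# a candidate K and a restart index.  Keeps every RNG stream reproducible
# and distinct without the user managing per-fit seeds.
deriveSeed <- function(seed, markerIndex, K, init) {
  s <- (as.double(seed) * 1000003 + as.double(markerIndex) * 7919 +
        as.double(K) * 104729 + as.double(init) * 131) %% 2147483647
  as.integer(s)
}

# Ascending-mean relabeling with the deterministic tie-breaks:
# equal means ordered by ascending sigma, then ascending weight.
orderComponents <- function(means, sigmas, weights) {
  order(means, sigmas, weights)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
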