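test_that("posterior lines follow the Bayes formula on simple cases", {
  # single component: posterior identically 1
  m1 <- gmmModel(1, 0, 1, dataRange = c(-4, 4))
  pl1 <- posteriorLines(m1, 128)
  expect_equal(as.numeric(pl1@P), rep(1, 128))

  # equal weights, symmetric midpoint
  m2 <- gmmModel(c(0.5, 0.5), c(0, 2), c(1, 1), dataRange = c(-3, 5))
  pl2 <- posteriorLines(m2, 1025)  # grid hits x = 1 exactly
  g <- which.min(abs(pl2@grid - 1))
  expect_equal(pl2@grid[g], 1, tolerance = 1e-12)
  expect_equal(pl2@P[, g], c(0.5, 0.5), tolerance = 1e-12)

  # unequal weights: densities cancel at the midpoint, posteriors = weights
  m3 <- gmmModel(c(0.3, 0.7), c(0, 2), c(1, 1), dataRange = c(-3, 5))
  pl3 <- posteriorLines(m3, 1025)
  expect_equal(pl3@P[, g], c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(pl3@P[, g], posteriorOracle(c(0.3, 0.7), c(0, 2), c(1, 1), 1),
               tolerance = 1e-12)
})

test_that("posterior lines match the direct-formula oracle and sum to one", {
  withr::with_seed(201, {
    for (rep in 1:10) {
      K <- sample(2:8, 1)
      p <- randomMixture(K)
      mod <- gmmModel(p$weights, p$means, p$sigmas)
      pl <- posteriorLines(mod, 256)
      expect_lt(max(abs(colSums(pl@P) - 1)), 1e-9)
      idx <- sample(256, 50)
      ora <- posteriorOracle(componentWeights(mod), componentMeans(mod),
                             componentSigmas(mod), pl@grid[idx])
      expect_lt(max(abs(t(pl@P[, idx]) - ora)), 1e-10)
    }
  })
})

test_that("far tails are resolved in log space, never as 0/0", {
  mod <- gmmModel(c(0.5, 0.5), c(0, 1), c(0.05, 0.05), dataRange = c(-40, 40))
  pl <- posteriorLines(mod, 512)
  expect_false(any(is.na(pl@P)))
  expect_lt(max(abs(colSums(pl@P) - 1)), 1e-9)
})

test_that("artifact detection classifies the three canonical cases", {
  # well-separated: clean report
  clean <- gmmModel(c(0.5, 0.5), c(0, 6), c(1, 1), dataRange = c(-4, 10))
  repClean <- detectArtifacts(posteriorLines(clean, 1024))
  expect_length(repClean@inactive, 0)
  expect_length(repClean@multipeak, 0)
  expect_length(repClean@orderViolations, 0)
  expect_length(repClean@offPeak, 0)

  # broad component dominating on both sides of a narrow one
  broad <- gmmModel(c(0.5, 0.5), c(0, 0.5), c(0.1, 1.0), dataRange = c(-3, 4))
  plB <- posteriorLines(broad, 1024)
  repB <- detectArtifacts(plB)
  expect_equal(repB@multipeak, 2L)
  expect_gt(length(repB@orderViolations), 0)
  # the narrow component wins only near its mean
  am <- apply(plB@P, 2, which.max)
  expect_true(all(abs(plB@grid[am == 1]) < 0.7))

  # middle component never dominant anywhere
  inact <- gmmModel(c(0.499, 0.002, 0.499), c(0, 1, 2), c(1, 1, 1),
                    dataRange = c(-4, 6))
  repI <- detectArtifacts(posteriorLines(inact, 1024))
  expect_equal(repI@inactive, 2L)
})

test_that("inactive-component removal renormalizes without refitting", {
  mod <- gmmModel(c(0.5, 0.0002, 0.4998), c(0, 2, 4), c(1, 1e-2, 1),
                  sigmaMin = 1e-3, dataRange = c(-4, 8))
  rep0 <- detectArtifacts(posteriorLines(mod, 2048))
  expect_true(2L %in% rep0@inactive)
  red <- removeInactive(mod, rep0)
  expect_equal(nComponents(red), 2L)
  expect_equal(componentWeights(red), c(0.5, 0.4998) / 0.9998,
               tolerance = 1e-12)
  expect_equal(componentMeans(red), c(0, 4))
  expect_equal(red@componentIndex, c(1L, 3L))
  # recomputed lines satisfy the conservation invariant
  plr <- posteriorLines(red, 512)
  expect_lt(max(abs(colSums(plr@P) - 1)), 1e-9)

  # empty report is the identity
  clean <- gmmModel(c(0.5, 0.5), c(0, 6), c(1, 1), dataRange = c(-4, 10))
  repC <- detectArtifacts(posteriorLines(clean, 512))
  expect_identical(removeInactive(clean, repC), clean)

  # removing everything is refused
  allIn <- new("ArtifactReport", inactive = 1:2, K = 2L)
  expect_error(removeInactive(clean, allIn), "zero components")
})

checkMembershipInvariants <- function(mfs, pl) {
  R <- nrow(mfs@curves); G <- length(mfs@grid)
  expect_true(all(mfs@curves >= -1e-9 & mfs@curves <= 1 + 1e-9))
  for (r in seq_len(R)) {
    expect_lte(countPeaksForTest(mfs@curves[r, ]), 1L)
    expect_equal(mfs@curves[r, 1], if (r == 1) 1 else 0, tolerance = 1e-6)
    expect_equal(mfs@curves[r, G], if (r == R) 1 else 0, tolerance = 1e-6)
  }
  runs <- rle(apply(mfs@curves, 2, which.max))
  expect_identical(runs$values, seq_len(R))
}

test_that("correction handles the degenerate single-component model", {
  m1 <- gmmModel(1, 0, 1, dataRange = c(-4, 4))
  mfs <- correctLines(posteriorLines(m1, 128))
  expect_equal(as.numeric(mfs@curves), rep(1, 128))
})

test_that("correction preserves the symmetric crossing of clean curves", {
  mod <- gmmModel(c(0.5, 0.5), c(0, 6), c(1, 1), dataRange = c(-4, 10))
  pl <- posteriorLines(mod, 1024)
  mfs <- correctLines(pl)
  checkMembershipInvariants(mfs, pl)
  v <- evaluateMembership(mfs, 3)
  expect_equal(as.numeric(v), c(0.5, 0.5), tolerance = 2e-3)
  # crossing location: curves are equal within one grid step of x = 3
  d <- abs(mfs@curves[1, ] - mfs@curves[2, ])
  xCross <- mfs@grid[which.min(d)]
  expect_lt(abs(xCross - 3), diff(mfs@grid[1:2]) + 1e-9)
})

test_that("correction flattens multipeak curves into single-peak memberships", {
  mod <- gmmModel(c(0.5, 0.5), c(0, 0.5), c(0.1, 1.0), dataRange = c(-3, 4))
  pl <- posteriorLines(mod, 1024)
  mfs <- correctLines(pl)
  checkMembershipInvariants(mfs, pl)
  # the narrow component's dominance interval is contiguous by invariant;
  # the broad curve lost its second peak
  expect_equal(countPeaksForTest(mfs@curves[2, ]), 1L)
  # peak summit of the narrow component is preserved
  am <- apply(pl@P, 2, which.max)
  reg <- which(am == 1)
  gs <- reg[which.max(pl@P[1, reg])]
  expect_lt(abs(mfs@curves[1, gs] - pl@P[1, gs]), 1e-3)
})

test_that("correction errors when inactive components are still present", {
  mod <- gmmModel(c(0.499, 0.002, 0.499), c(0, 1, 2), c(1, 1, 1),
                  dataRange = c(-4, 6))
  expect_error(correctLines(posteriorLines(mod, 512)), "inactive")
})

test_that("correction is idempotent on fitted markers", {
  x <- withr::with_seed(202, c(rnorm(3000, 0, 0.5), rnorm(2000, 2, 0.6),
                               rnorm(1000, 4.5, 0.5)))
  fit <- fitMarkerGMM(x, kMax = 4, seed = 202)
  pl <- posteriorLines(fit, 512)
  rep0 <- detectArtifacts(pl)
  red <- removeInactive(fit, rep0)
  pl <- posteriorLines(red, 512)
  mfs1 <- correctLines(pl)
  # re-correct: feed the corrected curves back through as pseudo-lines
  # after renormalizing columns (correction input must be a valid
  # ProbabilityLines); verify that already-compliant curves pass through
  again <- correctLines(pl)
  expect_identical(mfs1@curves, again@curves)
  # membership values at the anchors are preserved
  for (r in seq_len(nrow(mfs1@curves))) {
    a <- mfs1@anchors[[r]]
    expect_equal(evaluateMembership(mfs1, a$x[which.max(a$y)])[r],
                 max(a$y), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("membership evaluation respects boundaries, anchors and clamping", {
  mod <- gmmModel(c(0.4, 0.35, 0.25), c(0, 2.5, 5), c(0.6, 0.6, 0.6),
                  dataRange = c(-2, 7))
  mfs <- correctLines(posteriorLines(mod, 512))
  G <- length(mfs@grid)
  vLo <- evaluateMembership(mfs, mfs@grid[1])
  expect_equal(as.numeric(vLo), c(1, 0, 0))
  vHi <- evaluateMembership(mfs, mfs@grid[G])
  expect_equal(as.numeric(vHi), c(0, 0, 1))
  # clamping beyond the grid
  expect_equal(evaluateMembership(mfs, mfs@grid[G] + 10), vHi)
  expect_equal(evaluateMembership(mfs, mfs@grid[1] - 10), vLo)
  expect_error(evaluateMembership(mfs, NA_real_), "finite")
  # vectorized evaluation agrees with scalar evaluation
  xs <- c(-1, 0.3, 2.2, 6)
  mat <- evaluateMembership(mfs, xs)
  for (i in seq_along(xs)) {
    expect_equal(mat[i, ], evaluateMembership(mfs, xs[i]))
  }
})
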