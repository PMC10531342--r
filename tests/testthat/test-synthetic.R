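test_that("specification invariants are enforced", {
  pops <- data.frame(name = c("a", "b"), abundance = c(0.6, 0.4))
  mm <- list(list(means = c(0, 3), sigmas = c(0.5, 0.5)))
  expect_s4_class(syntheticSpec(pops, matrix(c(1L, 2L), 2, 1), mm, 100),
                  "SyntheticSpec")
  badAb <- data.frame(name = c("a", "b"), abundance = c(0.6, 0.5))
  expect_error(validObject(syntheticSpec(badAb, matrix(c(1L, 2L), 2, 1), mm, 100)),
               "sum to 1")
  expect_error(validObject(syntheticSpec(pops, matrix(c(1L, 3L), 2, 1), mm, 100)),
               "assignment")
})

test_that("benchmark presets are deterministic and structurally correct", {
  for (p in c("easy", "overlap", "rare_intermediate")) {
    s1 <- benchmarkSpec(p, nCells = 1000, seed = 3)
    s2 <- benchmarkSpec(p, nCells = 1000, seed = 3)
    expect_equal(s1, s2)
    expect_true(validObject(s1))
    for (j in seq_len(s1@nMarkers)) {
      w <- impliedWeights(s1, j)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
  rare <- benchmarkSpec("rare_intermediate", nCells = 1000, seed = 1)
  expect_equal(sum(rare@populations$abundance == 0.01), 1L)
  expect_equal(rare@rarePopulation, "rare")
  expect_equal(rare@definingMarker, 1L)
  # only the defining marker separates the rare population from both others
  sep <- vapply(seq_len(rare@nMarkers), function(j) {
    a <- rare@assignments[, j]
    a[2] != a[1] && a[2] != a[3]
  }, TRUE)
  expect_equal(which(sep), 1L)
  expect_error(benchmarkSpec("unknown"), "arg")
})

test_that("simulation draws from the assigned components reproducibly", {
  pops <- data.frame(name = "only", abundance = 1)
  mm <- list(list(means = 0, sigmas = 1))
  spec <- syntheticSpec(pops, matrix(1L, 1, 1), mm, nCells = 1000, seed = 5)
  m <- simulateCytof(spec)
  expect_true(isTransformed(m))
  expect_equal(unique(cellLabels(m)), "only")
  expect_lt(abs(mean(intensityValues(m))), 0.1)

  m2 <- simulateCytof(spec)
  expect_identical(intensityValues(m), intensityValues(m2))
})

test_that("rare-population counts stay within the binomial error bound", {
  pops <- data.frame(name = c("common", "rare"), abundance = c(0.99, 0.01))
  mm <- list(list(means = c(0, 4), sigmas = c(0.5, 0.5)))
  spec <- syntheticSpec(pops, matrix(c(1L, 2L), 2, 1), mm,
                        nCells = 100000, seed = 8)
  m <- simulateCytof(spec)
  nRare <- sum(cellLabels(m) == "rare")
  bound <- 3 * sqrt(100000 * 0.01 * 0.99)
  expect_lt(abs(nRare - 1000), bound)
})

test_that("empirical marginals satisfy the DKW bound for the true mixture", {
  spec <- benchmarkSpec("overlap", nCells = 20000, seed = 13)
  m <- simulateCytof(spec)
  n <- nrow(intensityValues(m))
  eps <- sqrt(log(2 / 0.01) / (2 * n))  # 99% DKW band
  for (j in seq_len(spec@nMarkers)) {
    x <- sort(intensityValues(m)[, j])
    ecdfVals <- seq_along(x) / n
    trueVals <- trueMarkerCDF(spec, j, x)
    expect_lt(max(abs(ecdfVals - trueVals)), eps + 1 / n)
  }
})

test_that("shared components collapse the fitted marginal, distinct ones split", {
  pops <- data.frame(name = c("p1", "p2"), abundance = c(0.5, 0.5))
  mm <- list(list(means = 1.5, sigmas = 0.5),          # shared on marker 1
             list(means = c(0, 3), sigmas = c(0.5, 0.5)))  # split on marker 2
  spec <- syntheticSpec(pops,
                        assignments = cbind(c(1L, 1L), c(1L, 2L)),
                        markerModels = mm, nCells = 4000, seed = 21)
  m <- simulateCytof(spec)
  f1 <- fitMarkerGMM(intensityValues(m)[, 1], kMax = 2, seed = 21,
                     markerIndex = 1)
  f2 <- fitMarkerGMM(intensityValues(m)[, 2], kMax = 2, seed = 21,
                     markerIndex = 2)
  expect_lte(nComponents(f1), 2L)
  expect_equal(nComponents(f2), 2L)
  expect_lt(max(abs(componentMeans(f2) - c(0, 3))), 0.1)
})

test_that("spec JSON serialization round-trips", {
  spec <- benchmarkSpec("rare_intermediate", nCells = 777, seed = 9)
  tf <- withr::local_tempfile(fileext = ".json")
  writeSyntheticSpec(spec, tf)
  back <- readSyntheticSpec(tf)
  expect_equal(back@populations$abundance, spec@populations$abundance)
  expect_equal(back@assignments, spec@assignments, ignore_attr = TRUE)
  expect_equal(back@markerModels[[1]]$means, spec@markerModels[[1]]$means)
  expect_identical(back@nCells, spec@nCells)
  expect_identical(back@definingMarker, spec@definingMarker)
  # identical draws from the round-tripped spec
  expect_identical(intensityValues(simulateCytof(back)),
                   intensityValues(simulateCytof(spec)))
})
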