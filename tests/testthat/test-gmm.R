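test_that("a single Gaussian is recovered with K = 1 and accurate moments", {
  x <- withr::with_seed(101, rnorm(20000))
  fit <- fitMarkerGMM(x, kMax = 3, seed = 101)
  expect_equal(nComponents(fit), 1L)
  expect_lt(abs(componentMeans(fit)), 0.05)
  expect_lt(abs(componentSigmas(fit) - 1), 0.05)
})

test_that("a well-separated two-component mixture is recovered", {
  x <- withr::with_seed(102, c(rnorm(10000, 0, 0.5), rnorm(10000, 4, 0.5)))
  fit <- fitMarkerGMM(x, kMax = 4, seed = 102)
  expect_equal(nComponents(fit), 2L)
  expect_lt(max(abs(componentMeans(fit) - c(0, 4))), 0.05)
  expect_lt(max(abs(componentWeights(fit) - c(0.5, 0.5))), 0.02)
  expect_lt(max(abs(componentSigmas(fit) - 0.5)), 0.05)
})

test_that("kMax = 1 gives the closed-form single-Gaussian MLE", {
  x <- withr::with_seed(103, rnorm(200, 3, 2))
  fit <- fitMarkerGMM(x, kMax = 1, seed = 1)
  n <- length(x)
  expect_equal(componentWeights(fit), 1)
  expect_equal(componentMeans(fit), mean(x), tolerance = 1e-12)
  expect_equal(componentSigmas(fit), sd(x) * sqrt((n - 1) / n),
               tolerance = 1e-12)
  # the sigma floor binds when the MLE sigma falls below it
  xc <- withr::with_seed(104, rnorm(100, 0, 1e-5))
  fitc <- fitMarkerGMM(xc, kMax = 1, sigmaMin = 1e-3, seed = 1)
  expect_equal(componentSigmas(fitc), 1e-3)
})

test_that("input validation: short, non-finite and degenerate inputs error", {
  expect_error(fitMarkerGMM(rnorm(50), kMax = 6), "at least 10\\*kMax")
  expect_error(fitMarkerGMM(c(rnorm(100), NA), kMax = 2), "finite")
  expect_error(fitMarkerGMM(rep(2, 100), kMax = 2), "degenerate")
})

test_that("log-likelihood matches closed forms and a summation oracle", {
  m1 <- gmmModel(1, 0, 1, dataRange = c(-4, 4))
  expect_equal(logLikGMM(m1, 0), log(1 / sqrt(2 * pi)), tolerance = 1e-12)

  # a two-component mixture with identical components collapses to K = 1
  m2 <- gmmModel(c(0.5, 0.5), c(1, 1), c(0.7, 0.7), dataRange = c(-3, 5))
  x <- withr::with_seed(105, rnorm(50, 1, 1))
  expect_equal(logLikGMM(m2, x), logLikGMM(gmmModel(1, 1, 0.7), x),
               tolerance = 1e-10)

  withr::with_seed(106, {
    p <- randomMixture(2)
    xx <- rnorm(50, 2, 2)
    m <- gmmModel(p$weights, p$means, p$sigmas)
    expect_equal(logLikGMM(m, xx),
                 logLikOracle(p$weights, p$means, p$sigmas, xx),
                 tolerance = 1e-10)
  })
})

test_that("the selected K minimizes the BIC trace and EM never decreases", {
  x <- withr::with_seed(107, c(rnorm(2000, 0, 0.5), rnorm(1000, 3, 0.5)))
  fit <- fitMarkerGMM(x, kMax = 4, seed = 107)
  trace <- bicTrace(fit)
  expect_length(trace, 4L)
  expect_equal(as.integer(names(which.min(trace))), nComponents(fit))
  expect_true(all(trace[as.character(nComponents(fit))] <= trace))
  expect_lt(fit@fitInfo$maxLogLikDecrease, 1e-8)
})

test_that("component relabeling is deterministic under permuted inputs", {
  w <- c(0.2, 0.5, 0.3); mu <- c(3, -1, 0.5); s <- c(0.3, 1, 0.6)
  ref <- gmmModel(w, mu, s)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    m <- gmmModel(w[perm], mu[perm], s[perm])
    expect_equal(componentMeans(m), componentMeans(ref))
    expect_equal(componentWeights(m), componentWeights(ref))
    expect_equal(componentSigmas(m), componentSigmas(ref))
  }
  # equal means: ties broken by ascending sigma, then ascending weight
  tie <- gmmModel(c(0.6, 0.4), c(1, 1), c(0.9, 0.2))
  expect_equal(componentSigmas(tie), c(0.2, 0.9))
})

test_that("fits are reproducible and serialization round-trips losslessly", {
  x <- withr::with_seed(108, c(rnorm(1500, 0, 0.6), rnorm(1500, 4, 0.8)))
  f1 <- fitMarkerGMM(x, kMax = 3, seed = 9)
  f2 <- fitMarkerGMM(x, kMax = 3, seed = 9)
  expect_identical(componentMeans(f1), componentMeans(f2))
  expect_identical(bicTrace(f1), bicTrace(f2))

  tf <- withr::local_tempfile(fileext = ".json")
  writeGMMModel(f1, tf)
  back <- readGMMModel(tf)
  expect_equal(componentWeights(back), componentWeights(f1), tolerance = 1e-15)
  expect_equal(componentMeans(back), componentMeans(f1), tolerance = 1e-15)
  expect_equal(componentSigmas(back), componentSigmas(f1), tolerance = 1e-15)
  expect_equal(bicTrace(back), bicTrace(f1), tolerance = 1e-15)
  expect_identical(back@nObs, f1@nObs)
  expect_identical(back@seed, f1@seed)
})

test_that("the fitted solution agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  x <- withr::with_seed(109, c(rnorm(3000, 0, 0.5), rnorm(2000, 3.5, 0.9)))
  fit <- fitMarkerGMM(x, kMax = 2, seed = 109)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(componentMeans(fit)), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit@logLik, mc$loglik, tolerance = 1e-3)
})
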