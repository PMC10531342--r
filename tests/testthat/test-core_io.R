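test_that("delimited reading parses, subsets and filters incomplete rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD45,B220", "1.0,2.0", "3.0,4.0"), tf)
  m <- readMarkerMatrix(tf)
  expect_s4_class(m, "MarkerMatrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(markerNames(m), c("CD45", "B220"))
  expect_equal(intensityValues(m), matrix(c(1, 3, 2, 4), 2, 2,
                                          dimnames = list(NULL, c("CD45", "B220"))))
  expect_false(isTransformed(m))

  msub <- readMarkerMatrix(tf, markerSubset = "B220")
  expect_equal(dim(msub), c(2L, 1L))
  expect_equal(intensityValues(msub)[, 1], c(2, 4), ignore_attr = TRUE)

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD45,B220", "1.0,2.0", "3.0,"), tf2)
  expect_message(m2 <- readMarkerMatrix(tf2), "dropped 1 row")
  expect_equal(dim(m2), c(1L, 2L))
  expect_equal(m2@nDropped, 1L)
})

test_that("delimited reading rejects malformed inputs", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD45,CD45", "1.0,2.0"), tf)
  expect_error(readMarkerMatrix(tf), "duplicate")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("CD45,B220", tf2)
  expect_error(readMarkerMatrix(tf2), "no data rows")

  expect_error(readMarkerMatrix(file.path(tempdir(), "absent.csv")),
               "not found")

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD45,pop", "1.0,B cell"), tf3)
  expect_error(readMarkerMatrix(tf3), "non-numeric")
  expect_silent(m <- readMarkerMatrix(tf3, labelColumn = "pop"))
  expect_equal(cellLabels(m), "B cell")
})

test_that("arcsinh transform matches the closed form and is refused twice", {
  m <- markerMatrix(matrix(c(0, 5, -5), 3, 1, dimnames = list(NULL, "CD45")))
  tr <- arcsinhTransform(m, cofactor = 5)
  expect_true(isTransformed(tr))
  expect_equal(intensityValues(tr)[, 1],
               c(0, log(1 + sqrt(2)), -log(1 + sqrt(2))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(arcsinhTransform(tr), "already")
  expect_error(arcsinhTransform(m, cofactor = 0), "positive")
  expect_error(arcsinhTransform(m, cofactor = -1), "positive")
})

test_that("arcsinh transform is strictly monotone and shape-preserving", {
  set.seed(41)
  v <- matrix(rnorm(600, sd = 50), 200, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  m <- markerMatrix(v, cellLabels = sample(letters[1:3], 200, TRUE))
  tr <- arcsinhTransform(m)
  expect_equal(dim(tr), dim(m))
  expect_equal(cellLabels(tr), cellLabels(m))
  for (j in 1:3) {
    expect_equal(order(intensityValues(tr)[, j]), order(v[, j]))
  }
})

test_that("delimited write/read round trip preserves 12+ significant digits", {
  set.seed(7)
  v <- matrix(exp(rnorm(60, sd = 3)) * sign(rnorm(60)), 20, 3,
              dimnames = list(NULL, c("CD3", "CD4", "CD8")))
  m <- markerMatrix(v, cellLabels = sample(c("T", "B"), 20, TRUE))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeMarkerMatrix(m, tf)
  back <- readMarkerMatrix(tf, labelColumn = "population")
  expect_equal(intensityValues(back), intensityValues(m), tolerance = 1e-13)
  expect_equal(cellLabels(back), cellLabels(m))
})

test_that("FCS files are read with stain-name channels and marker filtering", {
  set.seed(11)
  dat <- cbind(Time = seq_len(50), CD45 = rnorm(50, 10),
               B220 = rnorm(50, 5), Event_length = rep(20, 50))
  tf <- withr::local_tempfile(fileext = ".fcs")
  # $PnN holds instrument names, $PnS the stain names where present
  writeTestFCS(tf, dat, channels = c("Time", "Dd152", "Nd148", "Event_length"),
               stains = c("", "CD45", "B220", ""))
  m <- readMarkerMatrix(tf)
  expect_equal(markerNames(m), c("CD45", "B220"))
  expect_equal(intensityValues(m)[, "CD45"], dat[, "CD45"],
               tolerance = 1e-6, ignore_attr = TRUE)

  # explicit request brings back a non-marker channel
  mt <- readMarkerMatrix(tf, markerSubset = c("Time", "CD45"))
  expect_equal(markerNames(mt), c("Time", "CD45"))
  expect_error(readMarkerMatrix(tf, markerSubset = "CD99"), "not in file")
})

test_that("FCS reader rejects unsupported or corrupt files", {
  tf <- withr::local_tempfile(fileext = ".fcs")
  con <- file(tf, "wb")
  writeChar(sprintf("FCS2.0    %8d%8d%8d%8d%8d%8d", 58, 100, 0, 0, 0, 0),
            con, eos = NULL)
  close(con)
  expect_error(readMarkerMatrix(tf), "unsupported FCS version")
})
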