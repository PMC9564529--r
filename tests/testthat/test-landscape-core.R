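test_that("class areas count cells times cell area and skip nodata", {
  g <- grid_from(c(rep(2, 40), rep(1, 60)), nrow = 10)
  a <- areaKm2(classAreas(g))
  expect_equal(unname(a["forest"]), 40)
  expect_equal(unname(a["arable"]), 60)
  expect_equal(totalArea(classAreas(g)), 100)

  # all-nodata grid: zero everywhere
  gn <- LandUseGrid(matrix(-1L, 5, 5))
  expect_equal(unname(areaKm2(classAreas(gn))), rep(0, 6))

  # brute-force per-cell tally on a random grid
  set.seed(7)
  codes <- matrix(sample(c(-1L, 1:6), 400, replace = TRUE), 20, 20)
  g2 <- LandUseGrid(codes, cellArea = 0.25)
  tally <- numeric(6)
  for (i in seq_len(20)) for (j in seq_len(20)) {
    k <- codes[i, j]
    if (k != -1L) tally[k] <- tally[k] + 0.25
  }
  expect_equal(unname(areaKm2(classAreas(g2))), tally)

  # conserved under cell permutation
  perm <- sample(400)
  g3 <- LandUseGrid(matrix(codes[perm], 20, 20), cellArea = 0.25)
  expect_equal(areaKm2(classAreas(g3)), areaKm2(classAreas(g2)))
})

test_that("grid validity rejects bad codes and cell areas", {
  expect_error(LandUseGrid(matrix(9L, 2, 2)), "1\\.\\.6")
  expect_error(LandUseGrid(matrix(1L, 2, 2), cellArea = 0), "positive")
})

test_that("kappa agreement matches hand-computed confusion and the limits", {
  g <- grid_from(sample(1:6, 100, replace = TRUE), nrow = 10)
  expect_equal(kappaAgreement(g, g), 1)

  # 2-class balanced full-period shift: p_o = 0, p_e = 0.5, kappa = -1
  a <- grid_from(rep(c(1, 2), 50), nrow = 10)
  b <- grid_from(rep(c(2, 1), 50), nrow = 10)
  expect_equal(kappaAgreement(a, b), -1)

  # confusion {TT 40, TF 10, FT 10, FF 40}: p_o = .8, p_e = .5, kappa = .6
  va <- c(rep(1, 50), rep(2, 50))
  vb <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  expect_equal(kappaAgreement(grid_from(va, 10), grid_from(vb, 10)), 0.6)

  # cross-check against an independent implementation
  set.seed(42)
  x <- sample(1:4, 900, replace = TRUE)
  y <- ifelse(runif(900) < 0.7, x, sample(1:4, 900, replace = TRUE))
  ours <- kappaAgreement(grid_from(x, 30), grid_from(y, 30))
  ref <- e1071::classAgreement(table(x, y))$kappa
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("kappa requires comparable grids with overlapping valid cells", {
  a <- grid_from(rep(1, 100), 10)
  expect_error(kappaAgreement(a, LandUseGrid(matrix(1L, 5, 5))), "comparable")
  expect_error(kappaAgreement(a, LandUseGrid(matrix(-1L, 10, 10))),
               "overlapping")
})

test_that("masking keeps inside cells and blanks outside cells", {
  g <- grid_from(rep(3, 100), 10)
  expect_identical(landCodes(applyMask(g, RedLineMask(matrix(TRUE, 10, 10)))),
                   landCodes(g))
  allout <- applyMask(g, RedLineMask(matrix(FALSE, 10, 10)))
  expect_true(all(landCodes(allout) == -1L))

  # checkerboard halves the grass area of a constant grid
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  half <- applyMask(g, RedLineMask(chk))
  expect_equal(unname(areaKm2(classAreas(half))["grass"]), 50)

  expect_error(applyMask(g, RedLineMask(matrix(TRUE, 5, 5))), "shape")
})

test_that("rasters round-trip bit-identically in both formats", {
  set.seed(1)
  codes <- matrix(sample(c(-1L, 1:6), 400, replace = TRUE), 20, 20)
  g <- LandUseGrid(codes)
  for (ext in c(".asc", ".tif")) {
    f <- tempfile(fileext = ext)
    writeLandUseGrid(g, f)
    expect_identical(landCodes(readLandUseGrid(f)), codes, label = ext)
    unlink(f)
  }
})

test_that("reading rejects codes outside the class map", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -1", "1 9", "2 3"), f)
  expect_error(readLandUseGrid(f), "outside the class map|outside class map|class map")
  # constant grid reads cleanly
  f2 <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -1",
               "2 2 2", "2 2 2", "2 2 2"), f2)
  g <- readLandUseGrid(f2)
  expect_equal(unname(areaKm2(classAreas(g))["forest"]), 9)
  unlink(c(f, f2))
})

test_that("area vectors and driver surfaces round-trip through CSV/ASCII", {
  a <- AreaVector(c(10, 20, 30, 5, 2, 1))
  f <- tempfile(fileext = ".csv")
  writeAreaVector(a, f)
  expect_equal(areaKm2(readAreaVector(f)), areaKm2(a))
  unlink(f)

  m <- matrix(rnorm(100), 10, 10)
  f2 <- tempfile(fileext = ".asc")
  writeDriverSurface(m, f2)
  expect_equal(readDriverSurface(f2), m, tolerance = 1e-12)
  unlink(f2)
})
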