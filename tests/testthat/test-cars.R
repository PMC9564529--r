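test_that("neighborhood effect matches the windowed proportion definition", {
  g <- grid_from(rep(2, 9), 3)
  om <- neighborhoodEffect(g, 2L, 3L)
  expect_equal(om[2, 2], 1)          # saturated neighborhood
  expect_equal(om[1, 1], 1)          # clipped corner window, all forest

  # isolated cell: zero neighborhood for its class beyond distance one
  c1 <- matrix(1L, 7, 7); c1[4, 4] <- 2L
  om2 <- neighborhoodEffect(LandUseGrid(c1), 2L, 3L)
  expect_equal(om2[4, 4], 0)         # center excluded
  expect_equal(om2[4, 5], 1 / 8)
  expect_equal(om2[1, 1], 0)

  expect_error(neighborhoodEffect(g, 2L, 4L), "odd")

  # per-cell window loop oracle on a random grid with nodata
  set.seed(9)
  codes <- matrix(sample(c(-1L, 1:6), 15 * 12, replace = TRUE,
                         prob = c(0.1, rep(0.15, 6))), 15, 12)
  gg <- LandUseGrid(codes)
  om3 <- neighborhoodEffect(gg, 3L, 3L)
  for (i in seq_len(15)) for (j in seq_len(12)) {
    if (codes[i, j] == -1L) { expect_true(is.na(om3[i, j])); next }
    ii <- max(1, i - 1):min(15, i + 1)
    jj <- max(1, j - 1):min(12, j + 1)
    nb <- codes[ii, jj]; nb[which(ii == i), which(jj == j)] <- -2L
    valid_nb <- sum(nb != -1L & nb != -2L)
    k_nb <- sum(nb == 3L)
    expect_equal(om3[i, j], if (valid_nb > 0) k_nb / valid_nb else 0)
  }
})

test_that("the adaptive coefficient follows the gap-ratio inertia rule", {
  # shrinking gap: unchanged
  expect_equal(adaptiveCoefficient(1.5, 100, 95, 90), 1.5)
  # demand met exactly: unchanged
  expect_equal(adaptiveCoefficient(2, 100, 100, 90), 2)
  # growing deficit doubles the ratio: D doubles (pre-clip)
  expect_equal(adaptiveCoefficient(1, 100, 80, 90), 1 * (20 / 10))
  # clipping
  expect_equal(adaptiveCoefficient(8, 100, 0, 99), 10)
  expect_equal(adaptiveCoefficient(1, 100, 101, 100.0001), 10)
})

test_that("overall probability composes its factors elementwise", {
  P <- matrix(0.5, 2, 2); om <- matrix(0.5, 2, 2)
  expect_equal(overallProbability(P, om, 1), matrix(0.25, 2, 2))

  # zero neighborhood and no qualifying draw: zero
  r <- matrix(c(0.9, 0.1, 0.6, 0.2), 2, 2)
  seeded <- overallProbabilitySeed(P, r, 0.5, 1)
  expect_equal(seeded, ifelse(r < 0.5, 0.5 * r * 0.5 * 1, 0))

  # hand-computed 4x4 toy with a fixed draw sequence
  set.seed(11)
  P4 <- matrix(runif(16), 4, 4)
  r4 <- matrix(runif(16), 4, 4)
  manual <- matrix(0, 4, 4)
  for (i in 1:16) if (r4[i] < P4[i]) manual[i] <- P4[i] * r4[i] * 0.5 * 2
  expect_equal(overallProbabilitySeed(P4, r4, 0.5, 2), manual)
})

test_that("null allocation returns the base grid unchanged", {
  l <- generateLandscape(small_params(seed = 31L))
  dem <- areaKm2(classAreas(l$t1))
  res <- allocateLand(l$t1, flat_probs(dim(l$t1)), dem)
  expect_identical(landCodes(res$grid), landCodes(l$t1))
  expect_true(res$converged)
})

test_that("allocation moves exactly the demanded cells and conserves area", {
  # move 10 cells from grass (3) to forest (2) under uniform probabilities
  set.seed(3)
  codes <- matrix(sample(c(2L, 3L), 400, replace = TRUE), 20, 20)
  g <- LandUseGrid(codes)
  a <- areaKm2(classAreas(g))
  dem <- a; dem[2] <- a[2] + 10; dem[3] <- a[3] - 10
  res <- allocateLand(g, flat_probs(c(20, 20)), dem,
                      params = carsParams(seed = 7, demandTolerance = 0))
  out <- areaKm2(classAreas(res$grid))
  expect_equal(unname(out), unname(dem))
  expect_equal(sum(landCodes(res$grid) != codes), 10)
  # total conserved at every logged iteration
  expect_true(all(abs(rowSums(res$areaLog) - 400) < 1e-9))
})

test_that("demand totals, rules and reachability are enforced", {
  l <- generateLandscape(small_params(seed = 33L))
  dem <- areaKm2(classAreas(l$t1))
  expect_error(allocateLand(l$t1, flat_probs(dim(l$t1)), dem + 100),
               "does not match")

  # growth of residential is unreachable under the default rules
  dem2 <- dem; dem2[5] <- dem2[5] + 20; dem2[2] <- dem2[2] - 20
  expect_error(allocateLand(l$t1, flat_probs(dim(l$t1)), dem2),
               "residential")

  # freezing every arable cell makes arable shrinkage unreachable
  frozen <- landCodes(l$t1) == 1L
  dem3 <- dem; dem3[1] <- dem3[1] - 20; dem3[2] <- dem3[2] + 20
  expect_error(allocateLand(l$t1, flat_probs(dim(l$t1)), dem3,
                            transitionRules(frozenMask = frozen)),
               "arable")
})

test_that("frozen and built cells are bit-identical through allocation", {
  l <- generateLandscape(small_params(seed = 35L))
  base <- areaKm2(classAreas(l$t1))
  dem <- base
  dem[2] <- base[2] + 40; dem[3] <- base[3] - 40
  frozen <- maskInside(l$redline) & landCodes(l$t1) == 1L
  res <- allocateLand(l$t1, flat_probs(dim(l$t1)), dem,
                      transitionRules(frozenMask = frozen),
                      carsParams(seed = 2, demandTolerance = 0))
  out <- landCodes(res$grid)
  expect_identical(out[frozen], landCodes(l$t1)[frozen])
  built <- landCodes(l$t1) %in% c(5L, 6L)
  expect_identical(out[built], landCodes(l$t1)[built])
  expect_equal(unname(areaKm2(classAreas(res$grid))), unname(dem))
})

test_that("with no random seeding, growth stays adjacent to existing patches", {
  set.seed(5)
  # one forest patch in a grass sea; forest must grow only at its border
  codes <- matrix(3L, 30, 30)
  codes[14:16, 14:16] <- 2L
  g <- LandUseGrid(codes)
  dem <- areaKm2(classAreas(g))
  dem[2] <- dem[2] + 20; dem[3] <- dem[3] - 20
  res <- allocateLand(g, flat_probs(c(30, 30)), dem,
                      params = carsParams(seed = 4,
                                          expansionCoefficient = 0,
                                          demandTolerance = 0))
  new_forest <- which(landCodes(res$grid) == 2L & codes != 2L)
  om0 <- neighborhoodEffect(g, 2L, 3L)
  # every converted cell had a forest neighbor at some point of the growth;
  # at least the first ring must touch the original patch
  grown <- landCodes(res$grid) == 2L
  expect_equal(sum(grown), 29)
  # connectivity: the grown patch is a single connected component containing
  # the seed patch (flood fill)
  comp <- matrix(FALSE, 30, 30); comp[15, 15] <- TRUE
  repeat {
    nxt <- comp
    idx <- which(comp, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 30 && jj >= 1 && jj <= 30 && grown[ii, jj])
          nxt[ii, jj] <- TRUE
      }
    }
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  expect_equal(sum(comp), sum(grown))
})

test_that("scenario runs are reproducible and report diagnostics", {
  l <- generateLandscape(small_params(seed = 40L))
  base <- areaKm2(classAreas(l$t1))
  dem <- base; dem[1] <- base[1] + 30; dem[2] <- base[2] - 30
  r1 <- runScenario(l$t0, l$t1, l$drivers, dem,
                    params = carsParams(seed = 9), M = 20L,
                    nPerClass = 500L)
  r2 <- runScenario(l$t0, l$t1, l$drivers, dem,
                    params = carsParams(seed = 9), M = 20L,
                    nPerClass = 500L)
  expect_identical(landCodes(r1$grid), landCodes(r2$grid))
  expect_true(r1$diagnostics$converged)
  expect_true(r1$diagnostics$kappaVsBase >= -1 &&
              r1$diagnostics$kappaVsBase <= 1)
  expect_s4_class(r1$diagnostics$areas, "AreaVector")
})
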