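make_driver_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(d1 = runif(n), d2 = runif(n), d3 = runif(n))
}

test_that("expansion extraction marks exactly the conversions into a class", {
  l <- generateLandscape(small_params(seed = 4L))
  # no change: no positives anywhere
  e_same <- extractExpansion(l$t0, l$t0, 3L)
  expect_equal(sum(e_same == 1L, na.rm = TRUE), 0)

  # single flip 1 -> 2
  c0 <- matrix(1L, 5, 5); c1 <- c0; c1[3, 3] <- 2L
  g0 <- LandUseGrid(c0); g1 <- LandUseGrid(c1)
  e2 <- extractExpansion(g0, g1, 2L)
  expect_equal(sum(e2 == 1L, na.rm = TRUE), 1)
  expect_equal(e2[3, 3], 1L)
  e1 <- extractExpansion(g0, g1, 1L)
  expect_equal(sum(e1 == 1L, na.rm = TRUE), 0)
  # cells already of the class are excluded from sampling eligibility
  expect_true(all(is.na(extractExpansion(g1, g1, 2L)[3, 3])))

  # per-cell loop oracle on a random pair
  a0 <- landCodes(l$t0); a1 <- landCodes(l$t1)
  ek <- extractExpansion(l$t0, l$t1, 5L)
  for (idx in sample(length(a0), 200)) {
    expected <- if (a0[idx] == 5L) NA_integer_
                else if (a1[idx] == 5L) 1L else 0L
    expect_identical(ek[idx], expected)
  }

  # positives over all classes partition the changed cells
  tot_pos <- sum(vapply(1:6, function(k)
    sum(extractExpansion(l$t0, l$t1, k) == 1L, na.rm = TRUE), numeric(1)))
  expect_equal(tot_pos, sum(a0 != a1))
})

test_that("training sampling is balanced, capped and deterministic", {
  l <- generateLandscape(small_params(seed = 8L))
  e <- extractExpansion(l$t0, l$t1, 2L)
  npos <- sum(e == 1L, na.rm = TRUE)
  stopifnot(npos > 10, npos < 50000)

  # request far more than available positives: capped at equal classes
  smp <- sampleTraining(e, l$drivers, nPerClass = 10 * npos, seed = 3L)
  expect_equal(sum(smp$label == "1"), npos)
  expect_equal(sum(smp$label == "0"), npos)

  smp2 <- sampleTraining(e, l$drivers, nPerClass = 10 * npos, seed = 3L)
  expect_identical(smp, smp2)

  # uniform draw mirrors the map's label frequency within binomial error
  smp3 <- sampleTraining(e, l$drivers, nPerClass = 1000L,
                         strategy = "uniform", seed = 5L)
  p_map <- npos / sum(!is.na(e))
  p_smp <- mean(smp3$label == "1")
  expect_lt(abs(p_smp - p_map), 3 * sqrt(p_map * (1 - p_map) / 1000) + 0.01)

  # zero positives is an error naming the class
  e_none <- extractExpansion(l$t0, l$t0, 4L)
  expect_error(sampleTraining(e_none, l$drivers), "water")
})

test_that("growth models reproduce the vote-ratio definition", {
  # separable toy with a margin: positive iff d1 > 0.55, negative below 0.45
  df <- make_driver_frame(400, seed = 2)
  df$d1 <- ifelse(df$d1 > 0.5, 0.55 + df$d1 / 2, df$d1 * 0.9)
  lab <- factor(as.integer(df$d1 > 0.5), levels = c(0, 1))
  smp <- data.frame(cell = seq_len(400), label = lab, df)
  attr(smp, "landClass") <- 2L
  mod <- fitGrowthModel(smp, M = 50L, seed = 1L)
  stack <- DriverStack(list(d1 = matrix(df$d1, 20), d2 = matrix(df$d2, 20),
                            d3 = matrix(df$d3, 20)),
                       needsGroup = list(d1 = "security", d2 = "material",
                                         d3 = "spiritual"))
  P <- probSurface(growthProbability(mod, stack))
  expect_true(all(P[matrix(lab == "1", 20)] >= 0.9))
  expect_true(all(P[matrix(lab == "0", 20)] <= 0.1))

  # single tree votes 0 or 1 only
  mod1 <- fitGrowthModel(smp, M = 1L, seed = 1L)
  P1 <- probSurface(growthProbability(mod1, stack))
  expect_true(all(P1 %in% c(0, 1)))

  # vote-count oracle: tally the per-tree predicted labels directly
  newdata <- data.frame(d1 = as.vector(stack@surfaces$d1),
                        d2 = as.vector(stack@surfaces$d2),
                        d3 = as.vector(stack@surfaces$d3))
  per_tree <- predict(mod@forest, newdata, predict.all = TRUE)$individual
  manual <- matrix(rowMeans(per_tree == "1"), 20)
  expect_equal(P, manual, tolerance = 1e-12)

  # single-label samples are rejected
  smp_bad <- smp; smp_bad$label <- factor(rep(0, 400), levels = c(0, 1))
  expect_error(fitGrowthModel(smp_bad), "single label")

  # missing driver is an error
  stack2 <- DriverStack(list(d1 = matrix(df$d1, 20)),
                        needsGroup = list(d1 = "security"))
  expect_error(growthProbability(mod, stack2), "missing")
})

test_that("probability surfaces are bounded and invariant to driver order", {
  l <- generateLandscape(small_params(seed = 12L))
  e <- extractExpansion(l$t0, l$t1, 1L)
  smp <- sampleTraining(e, l$drivers, 1000L, seed = 2L)
  mod <- fitGrowthModel(smp, M = 30L, seed = 2L)
  P <- probSurface(growthProbability(mod, l$drivers))
  expect_true(all(P >= 0 & P <= 1))

  shuffled <- DriverStack(surfaces(l$drivers)[rev(driverNames(l$drivers))])
  P2 <- probSurface(growthProbability(mod, shuffled))
  expect_identical(P, P2)
})

test_that("driver importance normalizes and aggregates into needs groups", {
  df <- make_driver_frame(400, seed = 6)
  lab <- factor(as.integer(df$d1 + 0.2 * df$d2 > 0.6), levels = c(0, 1))
  smp <- data.frame(cell = seq_len(400), label = lab, df)
  attr(smp, "landClass") <- 1L
  mod <- fitGrowthModel(smp, M = 50L, seed = 3L)
  groups <- list(d1 = "security", d2 = c("security", "material"),
                 d3 = "spiritual")
  imp <- driverImportance(mod, groups = groups)
  expect_equal(sum(imp$driver), 1)
  expect_equal(sum(imp$group), 1)
  # the shared driver splits half-and-half between its two groups
  expect_equal(unname(imp$group["security"]),
               unname(imp$driver["d1"] + imp$driver["d2"] / 2))
  expect_equal(names(which.max(imp$driver)), "d1")
})

test_that("known dominant drivers are recovered on synthetic landscapes", {
  # moderate-size recovery check; the acceptance suite runs the full design
  wins <- 0
  for (s in 1:3) {
    l <- generateLandscape(landscapeParams(
      rows = 120, cols = 120, classFractions = rep(1 / 6, 6),
      driverEffects = dominant_effects(2L, "dem"), changeFraction = 0.1,
      seed = 20 + s))
    e <- extractExpansion(l$t0, l$t1, 2L)
    smp <- sampleTraining(e, l$drivers, 3000L, seed = s)
    mod <- fitGrowthModel(smp, M = 50L, seed = s)
    if (names(which.max(driverImportance(mod)$driver)) == "dem")
      wins <- wins + 1
  }
  expect_gte(wins, 2)
})
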