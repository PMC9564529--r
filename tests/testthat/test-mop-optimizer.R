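test_that("scenario LPs carry the published objective coefficients", {
  expect_equal(buildLp("security")$objective, c(0.02, 0.08, 0.45, 0.16, 0, 0))
  expect_equal(buildLp("material")$objective,
               c(362.33, 13.56, 168.47, 235.78, 45783.88, 67582.55))
  expect_equal(buildLp("spiritual")$objective,
               c(0.33, 1, 0.34, 0.83, 0, 0) / 33481.23)
  expect_error(buildLp("LD"), "linear projection")
  expect_error(buildLp("utopia"), "unknown scenario")
})

test_that("simplex solves trivial LPs and reports status honestly", {
  lp1 <- list(objective = c(1, 0, 0, 0, 0, 0),
              A1 = matrix(c(1, 0, 0, 0, 0, 0), 1), b1 = 5,
              scenario = "security")
  d1 <- solveLp(lp1)
  expect_equal(solverStatus(d1), "optimal")
  expect_equal(unname(areaKm2(demandAreas(d1))[1]), 5)

  lp2 <- list(objective = c(1, 1, 0, 0, 0, 0),
              A3 = matrix(c(1, 1, 0, 0, 0, 0), 1), b3 = 10,
              A1 = matrix(c(1, 0, 0, 0, 0, 0), 1), b1 = 3,
              scenario = "security")
  d2 <- solveLp(lp2)
  expect_equal(d2@objectiveValue, 10)

  # x1 >= 5 and x1 <= 1: infeasible, flagged not silent
  lp3 <- list(objective = c(1, 0, 0, 0, 0, 0),
              A1 = matrix(c(1, 0, 0, 0, 0, 0), 1), b1 = 1,
              A2 = matrix(c(1, 0, 0, 0, 0, 0), 1), b2 = 5,
              scenario = "security")
  expect_equal(solverStatus(solveLp(lp3)), "infeasible")
})

test_that("simplex agrees with vertex enumeration on random LPs", {
  set.seed(101)
  for (r in 1:25) {
    rlp <- random_lp(n_extra = 3L)
    ours <- solveLp(as_lp_desc(rlp))
    oracle <- vertex_enum_lp(rlp$objective, rlp$A, rlp$dir, rlp$b)
    expect_equal(solverStatus(ours), "optimal")
    expect_equal(ours@objectiveValue, oracle$value, tolerance = 1e-8)
  }
})

test_that("the four scenario optima match the oracle on the full system", {
  hd <- hechi_dir_form()
  for (sc in c("security", "material", "spiritual", "comprehensive")) {
    lp <- buildLp(sc)
    d <- solveLp(lp)
    expect_equal(solverStatus(d), "optimal")
    oracle <- vertex_enum_lp(lp$objective, hd$A, hd$dir, hd$b)
    expect_equal(d@objectiveValue, oracle$value,
                 tolerance = 1e-8 * max(1, abs(oracle$value)))
    # optimal solutions always pass the audit
    audit <- auditConstraints(demandAreas(d))
    expect_true(all(audit$satisfied))
  }
})

test_that("relaxing an upper bound never decreases the optimum", {
  base <- solveLp(buildLp("material"))@objectiveValue
  for (bump in c(10, 100)) {
    relaxed <- constraintSet(builtHigh = 143.27 + bump)
    v <- solveLp(buildLp("material", constraints = relaxed))@objectiveValue
    expect_gte(v, base - 1e-9)
    base <- v
  }
})

test_that("comprehensive scalarization reduces to single objectives at degenerate weights", {
  sc <- scalarizeComprehensive(weights = c(1, 0, 0))
  sec <- solveLp(buildLp("security"))
  d <- solveLp(list(objective = sc$objective,
                    A1 = buildLp("security")$A1, b1 = buildLp("security")$b1,
                    A2 = buildLp("security")$A2, b2 = buildLp("security")$b2,
                    A3 = buildLp("security")$A3, b3 = buildLp("security")$b3,
                    scenario = "comprehensive"))
  # same optimum: the scalarized objective is security / f1*
  expect_equal(d@objectiveValue * sc$ideals[["security"]],
               sec@objectiveValue, tolerance = 1e-8)

  # with unit ideals the scalarized objective is the plain weighted sum
  co <- objectiveCoefficients()
  w <- c(0.5, 0.3, 0.2)
  manual <- w[1] * co@security + w[2] * co@spiritualG[1:6] / co@regionTotalS +
            w[3] * co@materialE
  sc2 <- scalarizeComprehensive(weights = w)
  expect_equal(sc2$objective,
               w[1] * co@security / sc2$ideals[["security"]] +
               w[2] * (co@spiritualG[1:6] / co@regionTotalS) /
                 sc2$ideals[["spiritual"]] +
               w[3] * co@materialE / sc2$ideals[["material"]])
  expect_true(all(manual >= 0))
})

test_that("audits evaluate every published constraint row", {
  aud <- auditConstraints(scenarioAreas("security"))
  expect_true(aud$satisfied[aud$constraint == "total"])
  expect_equal(aud$lhs[aud$constraint == "total"], 33481.23, tolerance = 1e-9)

  # the published material column exceeds the residential upper bound
  aud2 <- auditConstraints(scenarioAreas("material"))
  built <- aud2[aud2$constraint == "built", ]
  expect_false(built$satisfied)
  expect_equal(built$lhs, 153.27)
  expect_lt(built$slack, 0)

  aud3 <- auditConstraints(rep(0, 6))
  expect_false(aud3$satisfied[aud3$constraint == "total"])
})
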