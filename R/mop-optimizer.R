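#' @include grey-forecast.R
NULL

#' Construct the constraint set for quantity-structure optimization
#'
#' Defaults are the published Hechi City 2035 bounds: a fixed regional total
#' of 33,481.23 km2; a population-capacity bracket
#' 4,523,100 <= 120 (x1+x2+x3) + 3000 (x5+x6) <= 4,618,000 with densities
#' 120 persons/km2 on ecological land and 3000 persons/km2 on built land; a
#' food-security floor x1 >= 3919.27; a residential bracket
#' 136.49 <= x5 <= 143.27; a water floor x4 >= 311.17; and an
#' ecological-footprint bracket 32,527.23 <= x1+x2+x3+x4 <= 32,787.82.
#' Every constraint can be toggled off via \code{enabled} so audits can run
#' against partial systems.
#'
#' @param totalArea,popLow,popHigh,popDensityEco,popDensityBuilt,arableMin
#'   numeric bounds, see description.
#' @param builtLow,builtHigh,waterMin,footprintLow,footprintHigh numeric
#'   bounds, see description.
#' @param enabled named logical toggles for the six constraint families.
#' @return a \linkS4class{ConstraintSet}.
#' @export
constraintSet <- function(totalArea = 33481.23,
                          popLow = 4523100, popHigh = 4618000,
                          popDensityEco = 120, popDensityBuilt = 3000,
                          arableMin = 3919.27,
                          builtLow = 136.49, builtHigh = 143.27,
                          waterMin = 311.17,
                          footprintLow = 32527.23, footprintHigh = 32787.82,
                          enabled = c(total = TRUE, population = TRUE,
                                      arable = TRUE, built = TRUE,
                                      water = TRUE, footprint = TRUE)) {
  new("ConstraintSet", totalArea = totalArea, popLow = popLow,
      popHigh = popHigh, popDensityEco = popDensityEco,
      popDensityBuilt = popDensityBuilt, arableMin = arableMin,
      builtLow = builtLow, builtHigh = builtHigh, waterMin = waterMin,
      footprintLow = footprintLow, footprintHigh = footprintHigh,
      enabled = enabled)
}

constraint_rows <- function(cs) {
  e <- function(i) replace(numeric(6), i, 1)
  pop <- cs@popDensityEco * (e(1) + e(2) + e(3)) +
         cs@popDensityBuilt * (e(5) + e(6))
  foot <- e(1) + e(2) + e(3) + e(4)
  list(
    total      = list(a = rep(1, 6), low = cs@totalArea, high = cs@totalArea),
    population = list(a = pop, low = cs@popLow, high = cs@popHigh),
    arable     = list(a = e(1), low = cs@arableMin, high = Inf),
    built      = list(a = e(5), low = cs@builtLow, high = cs@builtHigh),
    water      = list(a = e(4), low = cs@waterMin, high = Inf),
    footprint  = list(a = foot, low = cs@footprintLow, high = cs@footprintHigh))
}

#' Build the linear program for one needs scenario
#'
#' Assembles decision variables x1..x6 (class areas, km2), the scenario's
#' linear objective (security, material, spiritual, or the ideal-point
#' normalized weighted sum for the comprehensive scenario) and the enabled
#' constraint rows. The LD baseline is not an LP (see
#' \code{\link{linearProjection}}) and is rejected here.
#'
#' @param scenario one of "security", "material", "spiritual",
#'   "comprehensive".
#' @param coeffs an \linkS4class{ObjectiveCoefficients}.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @param weights comprehensive-scenario simplex weights over (security,
#'   spiritual, material); default equal.
#' @return an LP description list with elements \code{objective},
#'   \code{A1,b1} (<= rows), \code{A2,b2} (>= rows), \code{A3,b3} (= rows),
#'   \code{scenario}; non-negativity is implicit.
#' @export
buildLp <- function(scenario, coeffs = objectiveCoefficients(),
                    constraints = constraintSet(),
                    weights = c(1, 1, 1) / 3) {
  if (identical(scenario, "LD"))
    stopf("LD is a linear projection, not an LP; use linearProjection()")
  objective <- switch(scenario,
    security = coeffs@security,
    material = coeffs@materialE,
    spiritual = coeffs@spiritualG[1:6] / coeffs@regionTotalS,
    comprehensive =
      scalarizeComprehensive(coeffs, constraints, weights)$objective,
    stopf("unknown scenario '%s'", scenario))
  rows <- constraint_rows(constraints)
  rows <- rows[names(rows)[constraints@enabled[names(rows)]]]
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  for (r in rows) {
    if (is.finite(r$low) && is.finite(r$high) && r$low == r$high) {
      A3 <- rbind(A3, r$a); b3 <- c(b3, r$low)
    } else {
      if (is.finite(r$high)) { A1 <- rbind(A1, r$a); b1 <- c(b1, r$high) }
      if (is.finite(r$low) && r$low > 0) { A2 <- rbind(A2, r$a); b2 <- c(b2, r$low) }
    }
  }
  list(objective = objective, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
       A3 = A3, b3 = b3, scenario = scenario)
}

#' Solve a scenario linear program
#'
#' Maximizes the LP built by \code{\link{buildLp}} with the simplex method
#' (two-phase, Dantzig pivoting as implemented in \code{boot::simplex});
#' decision variables are implicitly non-negative. The algorithm is
#' deterministic, so repeated solves of the same LP agree bit-wise.
#'
#' @param lp an LP description from \code{\link{buildLp}}, or any list with
#'   the same fields.
#' @return a \linkS4class{ScenarioDemand}; \code{status} is "optimal",
#'   "infeasible" or "unbounded" (never a silent failure).
#' @export
solveLp <- function(lp) {
  res <- tryCatch(
    boot::simplex(a = lp$objective,
                  A1 = lp$A1, b1 = lp$b1,
                  A2 = lp$A2, b2 = lp$b2,
                  A3 = lp$A3, b3 = lp$b3,
                  maxi = TRUE, n.iter = 200 * (6 + length(lp$b1) +
                                               length(lp$b2) + length(lp$b3))),
    error = function(e) NULL)
  if (is.null(res))
    return(new("ScenarioDemand", scenario = lp$scenario,
               areas = AreaVector(rep(0, 6)), objectiveValue = NA_real_,
               status = "unbounded"))
  status <- if (res$solved == 1) "optimal"
            else if (res$solved == -1) "infeasible" else "unbounded"
  x <- if (status == "optimal") pmax(unname(res$soln[1:6]), 0) else rep(0, 6)
  new("ScenarioDemand", scenario = lp$scenario, areas = AreaVector(x),
      objectiveValue = if (status == "optimal") unname(res$value) else NA_real_,
      status = status)
}

#' Ideal-point scalarization of the comprehensive scenario
#'
#' Solves the three single-objective LPs to obtain the ideal values f1*, f2*,
#' f3*, then forms the normalized weighted-sum objective
#' sum_m w_m f_m(x) / f_m*. With default equal weights each objective
#' contributes its achievement ratio relative to its own optimum.
#'
#' @param coeffs an \linkS4class{ObjectiveCoefficients}.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @param weights simplex weights over (security, spiritual, material).
#' @return list with \code{objective} (numeric(6)) and \code{ideals}
#'   (named numeric(3) of f*).
#' @export
scalarizeComprehensive <- function(coeffs = objectiveCoefficients(),
                                   constraints = constraintSet(),
                                   weights = c(1, 1, 1) / 3) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  parts <- list(
    security = coeffs@security,
    spiritual = coeffs@spiritualG[1:6] / coeffs@regionTotalS,
    material = coeffs@materialE)
  ideals <- vapply(names(parts), function(sc) {
    d <- solveLp(buildLp(sc, coeffs, constraints))
    if (solverStatus(d) != "optimal")
      stopf("single-objective LP '%s' is %s", sc, solverStatus(d))
    d@objectiveValue
  }, numeric(1))
  if (any(ideals <= 0))
    stopf("ideal value(s) <= 0: cannot normalize (%s)",
          paste(names(ideals)[ideals <= 0], collapse = ", "))
  objective <- Reduce(`+`, Map(function(w, c, f) w * c / f,
                               weights, parts, ideals))
  list(objective = objective, ideals = ideals)
}

#' Audit an area vector against the constraint set
#'
#' Evaluates every constraint row (regardless of toggles) plus
#' non-negativity, reporting the left-hand-side value, the bounds, a
#' satisfaction flag at relative tolerance 1e-6 of the bound magnitude, and
#' the signed slack (distance to the nearest bound; negative = violated).
#'
#' @param x an \linkS4class{AreaVector} or numeric(6) of areas, km2.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @return data.frame with columns \code{constraint}, \code{lhs}, \code{low},
#'   \code{high}, \code{satisfied}, \code{slack}.
#' @export
auditConstraints <- function(x, constraints = constraintSet()) {
  v <- as_area6(x)
  rows <- constraint_rows(constraints)
  out <- lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    lhs <- sum(r$a * v)
    tol_lo <- 1e-6 * max(abs(r$low), 1)
    tol_hi <- if (is.finite(r$high)) 1e-6 * max(abs(r$high), 1) else 0
    sat <- lhs >= r$low - tol_lo && (!is.finite(r$high) || lhs <= r$high + tol_hi)
    slack <- min(lhs - r$low, if (is.finite(r$high)) r$high - lhs else Inf)
    data.frame(constraint = nm, lhs = lhs, low = r$low, high = r$high,
               satisfied = sat, slack = slack, stringsAsFactors = FALSE)
  })
  nn <- data.frame(constraint = "nonnegativity", lhs = min(v), low = 0,
                   high = Inf, satisfied = min(v) >= -1e-9, slack = min(v),
                   stringsAsFactors = FALSE)
  rbind(do.call(rbind, out), nn)
}

#' Solve one scenario's quantity structure
#'
#' Convenience wrapper: LD goes through \code{\link{linearProjection}} (the
#' caller must supply \code{areaSeries} and \code{years}); the other four
#' scenarios build and solve their LP.
#'
#' @param scenario scenario name.
#' @param coeffs,constraints,weights passed to \code{\link{buildLp}}.
#' @param areaSeries,years,targetYear historical areas for the LD baseline.
#' @return a \linkS4class{ScenarioDemand}.
#' @export
optimizeScenario <- function(scenario, coeffs = objectiveCoefficients(),
                             constraints = constraintSet(),
                             weights = c(1, 1, 1) / 3,
                             areaSeries = NULL, years = NULL,
                             targetYear = 2035) {
  if (identical(scenario, "LD")) {
    if (is.null(areaSeries) || is.null(years))
      stopf("LD scenario needs areaSeries and years")
    return(linearProjection(areaSeries, years, targetYear,
                            constraints@totalArea))
  }
  solveLp(buildLp(scenario, coeffs, constraints, weights))
}
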