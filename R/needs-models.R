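#' @include synthetic-data.R
NULL

#' Construct the objective coefficient set
#'
#' Defaults are the published Hechi City coefficients: the security
#' (ecological-footprint supply) objective 0.02 x1 + 0.08 x2 + 0.45 x3 +
#' 0.16 x4; the spiritual green equivalents g = (0.33, 1, 0.34, 0.83, 0, 0,
#' 0) normalized by the regional total S = 33,481.23 km2; and the material
#' economic benefits (362.33, 13.56, 168.47, 235.78, 45,783.88, 67,582.55)
#' per km2. All coefficients are configuration, not derived quantities.
#'
#' @param security numeric(6) footprint-supply coefficients.
#' @param spiritualG numeric(7) green equivalents g1..g7.
#' @param materialE numeric(6) economic benefit per km2.
#' @param regionTotalS regional total area, km2.
#' @return an \linkS4class{ObjectiveCoefficients}.
#' @export
objectiveCoefficients <- function(security = c(0.02, 0.08, 0.45, 0.16, 0, 0),
                                  spiritualG = c(0.33, 1, 0.34, 0.83, 0, 0, 0),
                                  materialE = c(362.33, 13.56, 168.47, 235.78,
                                                45783.88, 67582.55),
                                  regionTotalS = 33481.23) {
  new("ObjectiveCoefficients", security = security, spiritualG = spiritualG,
      materialE = materialE, regionTotalS = regionTotalS)
}

check_footprint_table <- function(table) {
  need <- c("land_type", "consumption", "productivity", "eq_factor")
  if (!all(need %in% names(table)))
    stopf("footprint table must have columns %s", paste(need, collapse = ","))
  if (any(table$consumption < 0)) stopf("consumption must be >= 0")
  if (any(table$productivity <= 0)) stopf("productivity must be > 0")
  if (any(table$eq_factor <= 0)) stopf("equilibrium factors must be > 0")
  invisible(TRUE)
}

#' Per-capita ecological footprint
#'
#' ef = sum over land types j and consumption items i of
#' r_j * c_i / p_i, where r_j is the land type's equilibrium factor, c_i the
#' annual per-capita consumption (kg/cap) and p_i the national mean
#' productivity (kg/hm2). Result in hm2 per capita.
#'
#' @param table footprint table as from \code{\link{generateFootprintTable}}.
#' @return per-capita footprint, hm2/cap.
#' @export
perCapitaFootprint <- function(table) {
  check_footprint_table(table)
  sum(table$eq_factor * table$consumption / table$productivity)
}

#' Total regional ecological footprint
#'
#' EF = N * ef: population times per-capita footprint, in hm2.
#'
#' @param ef per-capita footprint (hm2/cap).
#' @param N regional population (persons).
#' @return total footprint, hm2.
#' @export
totalFootprint <- function(ef, N) {
  stopifnot(ef >= 0, N >= 0)
  N * ef
}

as_area6 <- function(x) {
  if (is(x, "AreaVector")) unname(areaKm2(x))
  else {
    stopifnot(length(x) == .N_CLASSES)
    as.numeric(x)
  }
}

#' The three human-needs objectives
#'
#' Linear functionals of the six class areas (km2):
#' \describe{
#'   \item{securityObjective}{footprint-supply value
#'     f1 = 0.02 x1 + 0.08 x2 + 0.45 x3 + 0.16 x4 (default coefficients).}
#'   \item{spiritualObjective}{green-equivalent fraction
#'     f2 = (0.33 x1 + x2 + 0.34 x3 + 0.83 x4) / S, a dimensionless share of
#'     the forest-equivalent green amount in the regional total.}
#'   \item{materialObjective}{economic benefit
#'     f3 = sum(E_i x_i) in the printed RMB-per-km2 scale.}
#' }
#'
#' @param x an \linkS4class{AreaVector} or numeric(6) of areas, km2.
#' @param coeffs an \linkS4class{ObjectiveCoefficients}.
#' @return a single number.
#' @export
securityObjective <- function(x, coeffs = objectiveCoefficients()) {
  sum(as_area6(x) * coeffs@security)
}

#' @rdname securityObjective
#' @export
spiritualObjective <- function(x, coeffs = objectiveCoefficients()) {
  if (coeffs@regionTotalS <= 0) stopf("regionTotalS must be > 0")
  sum(as_area6(x) * coeffs@spiritualG[1:6]) / coeffs@regionTotalS
}

#' @rdname securityObjective
#' @export
materialObjective <- function(x, coeffs = objectiveCoefficients()) {
  sum(as_area6(x) * coeffs@materialE)
}
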