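#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' LandUseGrid: categorical land-use raster
#'
#' A single-band categorical raster of land-use class codes. Codes 1--6 map,
#' in canonical order, to arable, forest, grass, water, residential and
#' industrial-mining-transport land; nodata cells carry code -1. Cell areas
#' are stated directly in km2 per cell; the class performs no projection
#' arithmetic, so two grids are comparable only when their dimensions and
#' cell areas match exactly.
#'
#' @slot codes integer matrix of class codes (-1 = nodata, otherwise 1..6).
#' @slot cellArea positive scalar, km2 covered by one cell.
#' @slot classLabels character vector of the six class names, canonical order.
#' @slot epoch free-form year label (e.g. "2020").
#' @exportClass LandUseGrid
setClass("LandUseGrid",
  representation(codes = "matrix", cellArea = "numeric",
                 classLabels = "character", epoch = "character"),
  prototype(cellArea = 1, classLabels = .CLASS_LABELS, epoch = ""))

setValidity("LandUseGrid", function(object) {
  cd <- object@codes
  if (!is.numeric(cd)) return("codes must be a numeric/integer matrix")
  v <- cd[cd != .NODATA]
  if (length(v) && (any(v != as.integer(v)) || any(v < 1) || any(v > .N_CLASSES)))
    return("all non-nodata codes must be integers in 1..6")
  if (length(object@cellArea) != 1 || !is.finite(object@cellArea) ||
      object@cellArea <= 0)
    return("cellArea must be a single positive number")
  if (length(object@classLabels) != .N_CLASSES)
    return("classLabels must have length 6")
  TRUE
})

#' DriverStack: co-registered driver surfaces
#'
#' Continuous driver rasters (DEM, slope, distances to rail/road/river,
#' population density, GDP) sharing one grid geometry, each tagged with the
#' human-needs group(s) it expresses: security, spiritual and/or material.
#' A driver may belong to more than one group (population density and slope
#' do, in the default grouping).
#'
#' @slot surfaces named list of numeric matrices, identical dimensions.
#' @slot needsGroup named list: driver name -> character vector of groups.
#' @exportClass DriverStack
setClass("DriverStack",
  representation(surfaces = "list", needsGroup = "list"))

setValidity("DriverStack", function(object) {
  s <- object@surfaces
  if (!length(s)) return("at least one driver surface required")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("surfaces must be named")
  d <- dim(s[[1]])
  for (nm in names(s)) {
    if (!is.matrix(s[[nm]]) || !identical(dim(s[[nm]]), d))
      return("all surfaces must be matrices of identical dimensions")
  }
  grp <- object@needsGroup
  if (!all(names(s) %in% names(grp)))
    return("every driver needs a needs-group assignment")
  ok <- c("security", "spiritual", "material")
  for (nm in names(s)) {
    g <- grp[[nm]]
    if (!length(g) || !all(g %in% ok))
      return(sprintf("driver '%s' must belong to >=1 of %s", nm,
                     paste(ok, collapse = "/")))
  }
  TRUE
})

#' AreaVector: per-class areas in km2
#'
#' Six non-negative areas in canonical class order; the total is their sum.
#'
#' @slot areaKm2 named numeric vector, length 6, km2.
#' @exportClass AreaVector
setClass("AreaVector", representation(areaKm2 = "numeric"))

setValidity("AreaVector", function(object) {
  a <- object@areaKm2
  if (length(a) != .N_CLASSES) return("areaKm2 must have length 6")
  if (any(!is.finite(a)) || any(a < 0)) return("areas must be finite and >= 0")
  TRUE
})

#' RedLineMask: ecological red-line membership
#'
#' Boolean raster marking the cells inside the statutory ecological red line.
#'
#' @slot inside logical matrix (TRUE = inside the red line).
#' @exportClass RedLineMask
setClass("RedLineMask", representation(inside = "matrix"))

setValidity("RedLineMask", function(object) {
  if (!is.logical(object@inside)) return("inside must be a logical matrix")
  if (any(is.na(object@inside))) return("mask may not contain NA")
  TRUE
})

#' ProbabilitySurface: per-cell growth probability for one class
#'
#' The land-expansion vote ratio (trees voting for conversion / total trees)
#' evaluated at every cell, bounded in [0, 1]; NA on nodata cells.
#'
#' @slot prob numeric matrix in [0,1] (NA allowed).
#' @slot landClass integer class code 1..6 this surface refers to.
#' @exportClass ProbabilitySurface
setClass("ProbabilitySurface",
  representation(prob = "matrix", landClass = "integer"))

setValidity("ProbabilitySurface", function(object) {
  p <- object@prob
  v <- p[!is.na(p)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    return("probabilities must lie in [0,1]")
  k <- object@landClass
  if (length(k) != 1 || k < 1 || k > .N_CLASSES)
    return("landClass must be a single code in 1..6")
  TRUE
})

#' GrowthModel: per-class land-expansion ensemble
#'
#' One-vs-rest classification forest for a single land-use class; its
#' prediction at a cell is the fraction of trees voting that other classes
#' convert to this class there.
#'
#' @slot landClass integer class code 1..6.
#' @slot ntree number of trees M.
#' @slot forest fitted randomForest object.
#' @slot driverNames driver names in training order.
#' @exportClass GrowthModel
setClass("GrowthModel",
  representation(landClass = "integer", ntree = "integer",
                 forest = "ANY", driverNames = "character"))

setValidity("GrowthModel", function(object) {
  if (object@ntree < 1L) return("ntree must be >= 1")
  if (!length(object@driverNames)) return("driverNames must be non-empty")
  TRUE
})

#' GreyModel: fitted GM(1,1) grey forecasting model
#'
#' Single-variable grey model fitted on the first-order accumulated series
#' with trapezoidal background values; exact on exponential trends (up to an
#' O(a^3) bias in the development coefficient).
#'
#' @slot a development coefficient.
#' @slot b grey input (driving constant).
#' @slot x0First first observation of the raw series.
#' @slot n number of observations used in the fit.
#' @exportClass GreyModel
setClass("GreyModel",
  representation(a = "numeric", b = "numeric", x0First = "numeric",
                 n = "integer"))

#' ObjectiveCoefficients: the three needs objectives' coefficients
#'
#' Linear coefficients of the security (ecological-footprint), spiritual
#' (green-equivalent) and material (economic-benefit) objectives over the six
#' land classes, plus the fixed regional total area S. Defaults are the
#' published Hechi City values; all are overridable configuration.
#'
#' @slot security numeric(6), footprint-supply coefficients (classes 5-6 zero).
#' @slot spiritualG numeric(7), green equivalents g1..g7 (g5=g6=g7=0).
#' @slot materialE numeric(6), economic benefit per km2 (10^4 RMB/km2 scale as
#'   printed).
#' @slot regionTotalS regional total land area, km2.
#' @exportClass ObjectiveCoefficients
setClass("ObjectiveCoefficients",
  representation(security = "numeric", spiritualG = "numeric",
                 materialE = "numeric", regionTotalS = "numeric"))

setValidity("ObjectiveCoefficients", function(object) {
  if (length(object@security) != 6) return("security must have length 6")
  if (length(object@spiritualG) != 7) return("spiritualG must have length 7")
  if (length(object@materialE) != 6) return("materialE must have length 6")
  if (any(object@spiritualG[5:7] != 0)) return("g5, g6, g7 must be 0")
  if (any(object@security < 0) || any(object@spiritualG < 0) ||
      any(object@materialE < 0))
    return("coefficients must be >= 0")
  if (object@regionTotalS <= 0) return("regionTotalS must be > 0")
  TRUE
})

#' ConstraintSet: the quantity-structure constraint system
#'
#' The linear constraints bounding the six class areas: fixed regional total,
#' population-capacity bracket (density-weighted), arable floor, residential
#' bracket, water floor and an ecological-footprint bracket on the four
#' ecological classes. Each row can be toggled off so that audits can run
#' against partial systems. Defaults are the published Hechi City bounds.
#'
#' @slot totalArea km2, equality.
#' @slot popLow,popHigh persons bracketing 120(x1+x2+x3)+3000(x5+x6).
#' @slot popDensityEco persons/km2 on ecological classes (default 120).
#' @slot popDensityBuilt persons/km2 on built classes (default 3000).
#' @slot arableMin km2 floor on x1.
#' @slot builtLow,builtHigh km2 bracket on x5.
#' @slot waterMin km2 floor on x4.
#' @slot footprintLow,footprintHigh km2 bracket on x1+x2+x3+x4.
#' @slot enabled named logical vector of constraint toggles.
#' @exportClass ConstraintSet
setClass("ConstraintSet",
  representation(totalArea = "numeric", popLow = "numeric", popHigh = "numeric",
                 popDensityEco = "numeric", popDensityBuilt = "numeric",
                 arableMin = "numeric", builtLow = "numeric",
                 builtHigh = "numeric", waterMin = "numeric",
                 footprintLow = "numeric", footprintHigh = "numeric",
                 enabled = "logical"))

setValidity("ConstraintSet", function(object) {
  if (object@popLow > object@popHigh) return("popLow > popHigh")
  if (object@builtLow > object@builtHigh) return("builtLow > builtHigh")
  if (object@footprintLow > object@footprintHigh)
    return("footprintLow > footprintHigh")
  vals <- c(object@totalArea, object@popLow, object@popHigh, object@arableMin,
            object@builtLow, object@builtHigh, object@waterMin,
            object@footprintLow, object@footprintHigh)
  if (any(vals < 0)) return("all bounds must be >= 0")
  need <- c("total", "population", "arable", "built", "water", "footprint")
  if (!all(need %in% names(object@enabled)))
    return("enabled must name: total, population, arable, built, water, footprint")
  TRUE
})

#' ScenarioDemand: solved per-class area targets for one scenario
#'
#' @slot scenario one of security, material, spiritual, comprehensive, LD.
#' @slot areas AreaVector of the demanded class areas, km2.
#' @slot objectiveValue attained objective value (NA for fixture demands).
#' @slot status solver status: optimal, infeasible, unbounded or fixture.
#' @exportClass ScenarioDemand
setClass("ScenarioDemand",
  representation(scenario = "character", areas = "AreaVector",
                 objectiveValue = "numeric", status = "character"))

setValidity("ScenarioDemand", function(object) {
  ok <- c("security", "material", "spiritual", "comprehensive", "LD", "2020")
  if (!object@scenario %in% ok)
    return(sprintf("unknown scenario '%s'", object@scenario))
  if (!object@status %in% c("optimal", "infeasible", "unbounded", "fixture"))
    return("invalid status")
  TRUE
})

#' TransitionRules: allowed class transitions and frozen cells
#'
#' A 6x6 from->to permission matrix plus an optional frozen-cell mask. The
#' diagonal is always allowed. By default the built classes (residential,
#' industrial-mining-transport) neither convert out nor receive conversions,
#' mirroring the practice of freezing built land in allocation runs; growth
#' into built classes can be re-enabled by editing the allowed matrix.
#'
#' @slot allowed 6x6 logical matrix, rows = from, cols = to.
#' @slot frozenMask logical matrix of never-changing cells, or NULL.
#' @exportClass TransitionRules
setClass("TransitionRules",
  representation(allowed = "matrix", frozenMask = "matrixOrNULL"))

setValidity("TransitionRules", function(object) {
  al <- object@allowed
  if (!is.logical(al) || !identical(dim(al), c(.N_CLASSES, .N_CLASSES)))
    return("allowed must be a 6x6 logical matrix")
  if (!all(diag(al))) return("diagonal (self-transition) must be allowed")
  if (any(al[5L, -5L]) || any(al[6L, -6L]))
    return("built classes (5, 6) may only self-transition")
  if (!is.null(object@frozenMask) && !is.logical(object@frozenMask))
    return("frozenMask must be logical")
  TRUE
})

#' CarsParams: patch-generating cellular automaton parameters
#'
#' @slot patchThreshold per-class seeding threshold mu_k in [0,1] (default 0.5).
#' @slot expansionCoefficient probability of random patch seeding (default 0.1).
#' @slot window odd neighborhood window size (default 3).
#' @slot tauDecay decreasing-threshold decay delta in (0,1) (default 0.5).
#' @slot demandTolerance km2 convergence tolerance (NA = 0.1% of total area).
#' @slot maxIterations iteration cap.
#' @slot seed RNG seed for roulette and seeding draws.
#' @exportClass CarsParams
setClass("CarsParams",
  representation(patchThreshold = "numeric", expansionCoefficient = "numeric",
                 window = "integer", tauDecay = "numeric",
                 demandTolerance = "numeric", maxIterations = "integer",
                 seed = "integer"))

setValidity("CarsParams", function(object) {
  if (any(object@patchThreshold < 0) || any(object@patchThreshold > 1))
    return("patchThreshold must lie in [0,1]")
  if (object@expansionCoefficient < 0 || object@expansionCoefficient > 1)
    return("expansionCoefficient must lie in [0,1]")
  if (object@window < 3L || object@window %% 2L == 0L)
    return("window must be odd and >= 3")
  if (object@tauDecay <= 0 || object@tauDecay >= 1)
    return("tauDecay must lie in (0,1)")
  TRUE
})
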