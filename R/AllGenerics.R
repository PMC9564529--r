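#' @include AllClasses.R
NULL

#' @export
setGeneric("landCodes", function(x) standardGeneric("landCodes"))
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @export
setGeneric("epoch", function(x) standardGeneric("epoch"))
#' @export
setGeneric("areaKm2", function(x) standardGeneric("areaKm2"))
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @export
setGeneric("surfaces", function(x) standardGeneric("surfaces"))
#' @export
setGeneric("driverNames", function(x) standardGeneric("driverNames"))
#' @export
setGeneric("needsGroups", function(x) standardGeneric("needsGroups"))
#' @export
setGeneric("maskInside", function(x) standardGeneric("maskInside"))
#' @export
setGeneric("probSurface", function(x) standardGeneric("probSurface"))
#' @export
setGeneric("landClass", function(x) standardGeneric("landClass"))
#' @export
setGeneric("demandAreas", function(x) standardGeneric("demandAreas"))
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' Per-class areas of a land-use grid
#'
#' Counts the cells of each class and multiplies by the per-cell area; nodata
#' cells contribute to no class and are excluded from the total.
#'
#' @param grid a \linkS4class{LandUseGrid}.
#' @return an \linkS4class{AreaVector} (km2, canonical class order).
#' @export
setGeneric("classAreas", function(grid) standardGeneric("classAreas"))

#' Cohen's kappa agreement between two categorical grids
#'
#' Chance-corrected cellwise agreement (p_o - p_e)/(1 - p_e) over the cells
#' valid in both grids, with the expected agreement p_e taken from the
#' marginal class frequencies of the cross-tabulation.
#'
#' @param a,b comparable \linkS4class{LandUseGrid}s (same shape, cell area).
#' @return a single number in [-1, 1].
#' @export
setGeneric("kappaAgreement", function(a, b) standardGeneric("kappaAgreement"))

#' Restrict a grid to a red-line mask
#'
#' Cells outside the mask become nodata; inside cells are untouched.
#'
#' @param grid a \linkS4class{LandUseGrid}.
#' @param mask a \linkS4class{RedLineMask} of the same shape.
#' @return a \linkS4class{LandUseGrid}.
#' @export
setGeneric("applyMask", function(grid, mask) standardGeneric("applyMask"))
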