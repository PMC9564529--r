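#' @include AllGenerics.R
NULL

#' Construct a LandUseGrid
#'
#' @param codes integer matrix with values in \{-1, 1..6\}; -1 marks nodata.
#' @param cellArea km2 per cell (default 1).
#' @param classLabels six class names; the canonical order is arable, forest,
#'   grass, water, residential, industrial(-mining-transport).
#' @param epoch year label.
#' @return a \linkS4class{LandUseGrid}.
#' @examples
#' g <- LandUseGrid(matrix(2L, 3, 3))
#' areaKm2(classAreas(g))
#' @export
LandUseGrid <- function(codes, cellArea = 1, classLabels = .CLASS_LABELS,
                        epoch = "") {
  storage.mode(codes) <- "integer"
  new("LandUseGrid", codes = codes, cellArea = cellArea,
      classLabels = classLabels, epoch = as.character(epoch))
}

#' Construct an AreaVector
#'
#' @param areaKm2 numeric(6) of non-negative areas, canonical class order.
#' @param classLabels names for the six classes.
#' @return an \linkS4class{AreaVector}.
#' @export
AreaVector <- function(areaKm2, classLabels = .CLASS_LABELS) {
  a <- as.numeric(areaKm2)
  names(a) <- classLabels
  new("AreaVector", areaKm2 = a)
}

#' Construct a RedLineMask
#' @param inside logical matrix; TRUE marks cells inside the red line.
#' @return a \linkS4class{RedLineMask}.
#' @export
RedLineMask <- function(inside) new("RedLineMask", inside = inside)

#' Construct a DriverStack
#'
#' @param surfaces named list of numeric matrices, one per driver, identical
#'   dimensions.
#' @param needsGroup named list mapping each driver to its needs group(s)
#'   among "security", "spiritual", "material". Defaults to the standard
#'   grouping for the seven canonical drivers (population density and slope
#'   sit in two groups each).
#' @return a \linkS4class{DriverStack}.
#' @export
DriverStack <- function(surfaces, needsGroup = defaultNeedsGroups(names(surfaces))) {
  surfaces <- lapply(surfaces, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("DriverStack", surfaces = surfaces, needsGroup = needsGroup)
}

#' Default needs-group assignment of the canonical drivers
#'
#' DEM and population density express security needs; distance to river and
#' slope express spiritual needs; distances to rail and road, GDP, population
#' density and slope express material needs.
#'
#' @param drivers driver names to assign.
#' @return named list driver -> character vector of groups.
#' @export
defaultNeedsGroups <- function(drivers) {
  std <- list(
    dem         = "security",
    pop_density = c("security", "material"),
    dist_river  = "spiritual",
    slope       = c("spiritual", "material"),
    dist_rail   = "material",
    dist_road   = "material",
    gdp         = "material")
  out <- lapply(drivers, function(d) {
    if (d %in% names(std)) std[[d]] else "material"
  })
  names(out) <- drivers
  out
}

## ---- accessors -------------------------------------------------------------

#' @describeIn LandUseGrid code matrix accessor
#' @param x object.
#' @export
setMethod("landCodes", "LandUseGrid", function(x) x@codes)
#' @export
setMethod("cellArea", "LandUseGrid", function(x) x@cellArea)
#' @export
setMethod("classLabels", "LandUseGrid", function(x) x@classLabels)
#' @export
setMethod("epoch", "LandUseGrid", function(x) x@epoch)
#' @export
setMethod("dim", "LandUseGrid", function(x) dim(x@codes))

#' @export
setMethod("areaKm2", "AreaVector", function(x) x@areaKm2)
#' @export
setMethod("totalArea", "AreaVector", function(x) sum(x@areaKm2))

#' @export
setMethod("surfaces", "DriverStack", function(x) x@surfaces)
#' @export
setMethod("driverNames", "DriverStack", function(x) names(x@surfaces))
#' @export
setMethod("needsGroups", "DriverStack", function(x) x@needsGroup)
#' @export
setMethod("dim", "DriverStack", function(x) dim(x@surfaces[[1]]))

#' @export
setMethod("maskInside", "RedLineMask", function(x) x@inside)

#' @export
setMethod("probSurface", "ProbabilitySurface", function(x) x@prob)
#' @export
setMethod("landClass", "ProbabilitySurface", function(x) x@landClass)
#' @export
setMethod("landClass", "GrowthModel", function(x) x@landClass)
#' @export
setMethod("driverNames", "GrowthModel", function(x) x@driverNames)

#' @export
setMethod("demandAreas", "ScenarioDemand", function(x) x@areas)
#' @export
setMethod("solverStatus", "ScenarioDemand", function(x) x@status)

## ---- show methods ----------------------------------------------------------

setMethod("show", "LandUseGrid", function(object) {
  d <- dim(object@codes)
  nv <- sum(object@codes != .NODATA)
  cat(sprintf("LandUseGrid %dx%d, cellArea %g km2, epoch '%s'\n",
              d[1], d[2], object@cellArea, object@epoch))
  cat(sprintf("  valid cells: %d (%.1f km2)\n", nv, nv * object@cellArea))
})

setMethod("show", "AreaVector", function(object) {
  cat("AreaVector (km2):\n")
  print(round(object@areaKm2, 2))
  cat(sprintf("  total: %.2f km2\n", sum(object@areaKm2)))
})

setMethod("show", "DriverStack", function(object) {
  d <- dim(object@surfaces[[1]])
  cat(sprintf("DriverStack %dx%d with %d drivers: %s\n", d[1], d[2],
              length(object@surfaces),
              paste(names(object@surfaces), collapse = ", ")))
})

setMethod("show", "ScenarioDemand", function(object) {
  cat(sprintf("ScenarioDemand '%s' [%s], objective %s\n", object@scenario,
              object@status,
              if (is.na(object@objectiveValue)) "NA"
              else format(object@objectiveValue, big.mark = ",")))
  print(round(object@areas@areaKm2, 2))
})

setMethod("show", "GreyModel", function(object) {
  cat(sprintf("GreyModel GM(1,1): a = %.6g, b = %.6g (n = %d)\n",
              object@a, object@b, object@n))
})

## ---- core operations -------------------------------------------------------

# Comparability guard shared by kappa, expansion extraction and allocation.
checkComparable <- function(a, b) {
  if (!identical(dim(a@codes), dim(b@codes)))
    stopf("grids are not comparable: shapes %s vs %s",
          paste(dim(a@codes), collapse = "x"),
          paste(dim(b@codes), collapse = "x"))
  if (a@cellArea != b@cellArea)
    stopf("grids are not comparable: cell areas %g vs %g",
          a@cellArea, b@cellArea)
  invisible(TRUE)
}

#' @rdname classAreas
#' @export
setMethod("classAreas", "LandUseGrid", function(grid) {
  counts <- tabulate(grid@codes[grid@codes != .NODATA], nbins = .N_CLASSES)
  AreaVector(counts * grid@cellArea, grid@classLabels)
})

#' @rdname kappaAgreement
#' @export
setMethod("kappaAgreement", signature("LandUseGrid", "LandUseGrid"),
          function(a, b) {
  checkComparable(a, b)
  ok <- a@codes != .NODATA & b@codes != .NODATA
  if (!any(ok)) stopf("no overlapping non-nodata cells")
  ca <- factor(a@codes[ok], levels = 1:.N_CLASSES)
  cb <- factor(b@codes[ok], levels = 1:.N_CLASSES)
  tab <- table(ca, cb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(1)  # degenerate: a single class on both maps
  (po - pe) / (1 - pe)
})

#' @rdname applyMask
#' @export
setMethod("applyMask", signature("LandUseGrid", "RedLineMask"),
          function(grid, mask) {
  if (!identical(dim(grid@codes), dim(mask@inside)))
    stopf("mask shape %s does not match grid shape %s",
          paste(dim(mask@inside), collapse = "x"),
          paste(dim(grid@codes), collapse = "x"))
  codes <- grid@codes
  codes[!mask@inside] <- .NODATA
  LandUseGrid(codes, grid@cellArea, grid@classLabels, grid@epoch)
})
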