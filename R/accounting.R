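#' @include cars.R
NULL

#' Load the published scenario quantity-structure table
#'
#' The per-class optimized areas (km2) of the five scenarios plus the 2020
#' baseline, shipped as a versioned CSV fixture transcribed from the
#' published results. Scenario differences are always computed from these
#' columns, never hard-coded.
#'
#' @return data.frame with columns \code{class}, \code{y2020},
#'   \code{security}, \code{material}, \code{spiritual},
#'   \code{comprehensive}, \code{ld}.
#' @export
scenarioTable <- function() {
  path <- system.file("extdata", "table5.csv", package = "ecolandopt",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Extract one scenario column as an AreaVector
#'
#' @param scenario column name of \code{\link{scenarioTable}} ("y2020",
#'   "security", "material", "spiritual", "comprehensive" or "ld").
#' @return an \linkS4class{AreaVector}.
#' @export
scenarioAreas <- function(scenario) {
  tab <- scenarioTable()
  if (!scenario %in% names(tab)[-1])
    stopf("unknown scenario column '%s'", scenario)
  idx <- match(.CLASS_LABELS, tab$class)
  AreaVector(tab[[scenario]][idx])
}

#' Per-class change table between two area vectors
#'
#' delta = area_a - area_b per class; antisymmetric under swapping the two
#' inputs. Both vectors must share the canonical class ordering.
#'
#' @param a,b \linkS4class{AreaVector}s (or numeric(6)).
#' @param labels character(2) naming the two scenarios.
#' @return data.frame with columns \code{class}, \code{area_a},
#'   \code{area_b}, \code{delta} and attribute \code{labels}.
#' @export
changeTable <- function(a, b, labels = c("a", "b")) {
  av <- if (is(a, "AreaVector")) areaKm2(a) else setNames(as.numeric(a), .CLASS_LABELS)
  bv <- if (is(b, "AreaVector")) areaKm2(b) else setNames(as.numeric(b), .CLASS_LABELS)
  if (!identical(names(av), names(bv)))
    stopf("class orderings differ between the two area vectors")
  out <- data.frame(class = names(av), area_a = unname(av),
                    area_b = unname(bv), delta = unname(av - bv),
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- labels
  out
}

#' Red-line intersection report
#'
#' Intersects each scenario grid (and the baseline) with the ecological
#' red-line mask and tabulates per-class areas inside the line plus their
#' deltas against the masked baseline.
#'
#' @param grids named list of scenario \linkS4class{LandUseGrid}s.
#' @param baseline baseline \linkS4class{LandUseGrid} (e.g. the 2020 map).
#' @param mask a \linkS4class{RedLineMask}.
#' @return data.frame with columns \code{scenario}, \code{class},
#'   \code{area_km2} (inside the red line) and \code{delta_km2} (vs the
#'   masked baseline).
#' @export
redlineReport <- function(grids, baseline, mask) {
  base_in <- areaKm2(classAreas(applyMask(baseline, mask)))
  rows <- lapply(names(grids), function(sc) {
    a <- areaKm2(classAreas(applyMask(grids[[sc]], mask)))
    data.frame(scenario = sc, class = names(a), area_km2 = unname(a),
               delta_km2 = unname(a - base_in), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
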