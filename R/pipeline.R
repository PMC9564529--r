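#' @include accounting.R
NULL

default_pipeline_config <- function() {
  list(
    seed = 1L,
    synth = list(rows = 60L, cols = 60L, change_fraction = 0.1),
    scenarios = c("security", "material", "spiritual", "comprehensive", "ld"),
    demands = "table5",          # "table5" fixture or "solve"
    leas = list(trees = 50L, n_per_class = 2000L),
    cars = list(patch_threshold = 0.5, expansion_coefficient = 0.1,
                window = 3L, tau_decay = 0.5, max_iterations = 200L),
    out_dir = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# Rescale a fixture area vector onto a landscape: classes 1-4 take the
# fixture's relative proportions over the area left after the built classes
# (which the default transition rules freeze) keep their base areas.
scale_demand_to_landscape <- function(fixture, baseAreas) {
  f <- if (is(fixture, "AreaVector")) areaKm2(fixture) else fixture
  b <- if (is(baseAreas, "AreaVector")) areaKm2(baseAreas) else baseAreas
  out <- b
  eco <- 1:4
  free <- sum(b) - sum(b[-eco])
  out[eco] <- f[eco] / sum(f[eco]) * free
  AreaVector(out)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic landscape, obtains per-scenario demands (from the
#' packaged scenario table, rescaled to the landscape, or by solving the
#' scenario LPs and rescaling), fits the land-expansion models once on the
#' t0 -> t1 transition, allocates every scenario with the patch-growing CA,
#' and assembles area, change and red-line reports. With \code{out_dir} set,
#' writes \code{areas.csv}, \code{changes.csv}, \code{redline.csv} and
#' \code{run.json}.
#'
#' @param config nested configuration list, or the path of a YAML file with
#'   the same structure; omitted entries fall back to defaults (60x60 grid,
#'   fixture demands, all five scenarios).
#' @return list with the landscape, demands, per-scenario allocation
#'   results, and the three report data.frames.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)

  land <- generateLandscape(landscapeParams(
    rows = cfg$synth$rows, cols = cfg$synth$cols,
    changeFraction = cfg$synth$change_fraction, seed = cfg$seed))
  baseAreas <- classAreas(land$t1)

  fixture_cols <- c(security = "security", material = "material",
                    spiritual = "spiritual", comprehensive = "comprehensive",
                    ld = "ld")
  demands <- lapply(cfg$scenarios, function(sc) {
    raw <- if (identical(cfg$demands, "solve") && sc != "ld") {
      d <- optimizeScenario(if (sc == "ld") "LD" else sc)
      if (solverStatus(d) != "optimal") stopf("stage mop: scenario %s %s",
                                              sc, solverStatus(d))
      areaKm2(demandAreas(d))
    } else areaKm2(scenarioAreas(fixture_cols[[sc]]))
    scale_demand_to_landscape(raw, baseAreas)
  })
  names(demands) <- cfg$scenarios

  fit <- tryCatch(
    leasProbabilities(land$t0, land$t1, land$drivers,
                      M = cfg$leas$trees, nPerClass = cfg$leas$n_per_class,
                      seed = cfg$seed, onEmpty = "zero"),
    error = function(e) stopf("stage leas: %s", conditionMessage(e)))

  params <- carsParams(patchThreshold = cfg$cars$patch_threshold,
                       expansionCoefficient = cfg$cars$expansion_coefficient,
                       window = cfg$cars$window,
                       tauDecay = cfg$cars$tau_decay,
                       maxIterations = cfg$cars$max_iterations,
                       seed = cfg$seed)
  runs <- lapply(cfg$scenarios, function(sc) {
    tryCatch(
      allocateLand(land$t1, fit$probs, demands[[sc]],
                   rules = transitionRules(), params = params),
      error = function(e) stopf("stage cars (%s): %s", sc,
                                conditionMessage(e)))
  })
  names(runs) <- cfg$scenarios

  areas <- do.call(rbind, lapply(cfg$scenarios, function(sc) {
    a <- areaKm2(classAreas(runs[[sc]]$grid))
    data.frame(scenario = sc, class = names(a), area_km2 = unname(a))
  }))
  changes <- do.call(rbind, lapply(cfg$scenarios, function(sc) {
    ct <- changeTable(classAreas(runs[[sc]]$grid), baseAreas,
                      labels = c(sc, "base"))
    cbind(scenario = sc, ct)
  }))
  redline <- redlineReport(lapply(runs, `[[`, "grid"), land$t1, land$redline)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(areas, file.path(cfg$out_dir, "areas.csv"), row.names = FALSE)
    write.csv(changes, file.path(cfg$out_dir, "changes.csv"),
              row.names = FALSE)
    write.csv(redline, file.path(cfg$out_dir, "redline.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed,
           package_version = as.character(utils::packageVersion("ecolandopt")),
           scenarios = cfg$scenarios,
           iterations = lapply(runs, `[[`, "iterations"),
           converged = lapply(runs, `[[`, "converged")),
      file.path(cfg$out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  list(landscape = land, demands = demands, runs = runs, areas = areas,
       changes = changes, redline = redline, config = cfg)
}
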