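#' @include io.R
NULL

#' Parameters of the synthetic landscape generator
#'
#' The generator emulates a two-epoch categorical landscape whose class
#' transitions are driven by known driver surfaces, so that every downstream
#' stage (expansion extraction, growth-probability modelling, allocation)
#' can be tested against a known truth. Class fractions default to the
#' Hechi-like 2020 composition (forest-dominated karst landscape).
#'
#' @param rows,cols grid dimensions.
#' @param classFractions numeric(6) on the simplex; share of valid cells per
#'   class at the first epoch.
#' @param driverEffects 6 x 7 matrix of per-class logistic weights on the
#'   standardized drivers (columns: dem, slope, dist_rail, dist_road,
#'   dist_river, pop_density, gdp). Row k governs the propensity of a cell to
#'   convert to class k.
#' @param changeFraction share of valid cells that transition between the two
#'   epochs, in (0, 0.5] (0 allowed for the no-change limit).
#' @param cellArea km2 per cell.
#' @param seed RNG seed; the same seed yields bit-identical landscapes.
#' @return a validated parameter list of class "LandscapeParams".
#' @export
landscapeParams <- function(rows = 100L, cols = 100L,
                            classFractions = c(0.117, 0.744, 0.125, 0.009,
                                               0.004, 0.001),
                            driverEffects = defaultDriverEffects(),
                            changeFraction = 0.1, cellArea = 1, seed = 1L) {
  stopifnot(rows >= 10L, cols >= 10L)
  if (abs(sum(classFractions) - 1) > 1e-6)
    stopf("classFractions must sum to 1")
  if (changeFraction < 0 || changeFraction > 0.5)
    stopf("changeFraction must lie in [0, 0.5]")
  if (!identical(dim(driverEffects), c(6L, 7L)))
    stopf("driverEffects must be a 6x7 matrix")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 classFractions = classFractions,
                 driverEffects = driverEffects,
                 changeFraction = changeFraction, cellArea = cellArea,
                 seed = as.integer(seed)),
            class = "LandscapeParams")
}

#' Default per-class driver weights of the synthetic generator
#'
#' Encodes plausible landscape ecology: arable favors flat cells near roads,
#' forest high rugged ground, grass mid elevations away from people, water
#' proximity to rivers, residential dense populated road-accessible cells and
#' industrial-mining-transport land high-GDP rail-accessible cells.
#'
#' @return 6 x 7 numeric matrix (classes x drivers).
#' @export
defaultDriverEffects <- function() {
  drv <- c("dem", "slope", "dist_rail", "dist_road", "dist_river",
           "pop_density", "gdp")
  W <- matrix(0, 6, 7, dimnames = list(.CLASS_LABELS, drv))
  W["arable", c("slope", "dist_road")] <- c(-1.5, -1.0)
  W["forest", c("dem", "slope")] <- c(1.5, 1.0)
  W["grass", c("dem", "pop_density")] <- c(1.0, -0.8)
  W["water", "dist_river"] <- -2.0
  W["residential", c("pop_density", "dist_road")] <- c(2.0, -1.0)
  W["industrial", c("gdp", "dist_rail")] <- c(2.0, -1.0)
  W
}

# Smooth standardized random surface: a low-frequency random cosine mixture,
# spatially autocorrelated by construction.
smooth_field <- function(rows, cols, n_waves = 8L, max_freq = 3) {
  xs <- seq(0, 1, length.out = cols)
  ys <- seq(0, 1, length.out = rows)
  X <- matrix(xs, rows, cols, byrow = TRUE)
  Y <- matrix(ys, rows, cols)
  f <- matrix(0, rows, cols)
  for (h in seq_len(n_waves)) {
    u <- runif(1, 0.3, max_freq); v <- runif(1, 0.3, max_freq)
    if (runif(1) < 0.5) u <- -u
    ph <- runif(1, 0, 2 * pi)
    f <- f + runif(1, 0.5, 1) * cos(2 * pi * (u * X + v * Y) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

# Distance (in cell units, normalized) from each cell to the nearest of a few
# random straight routes across the grid; stands in for rail/road/river
# distance rasters.
route_distance <- function(rows, cols, n_routes = 2L) {
  X <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  Y <- matrix(seq_len(rows), rows, cols)
  d <- matrix(Inf, rows, cols)
  for (i in seq_len(n_routes)) {
    x0 <- runif(1, 1, cols); y0 <- runif(1, 1, rows)
    th <- runif(1, 0, pi)
    di <- abs((X - x0) * sin(th) - (Y - y0) * cos(th))
    d <- pmin(d, di)
  }
  d / max(d)
}

# Box-mean blur via integral images; used for the red-line mask dilation.
box_blur <- function(m, r = 3L) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  i0 <- pmax(seq_len(nr) - r, 0L); i1 <- pmin(seq_len(nr) + r, nr)
  j0 <- pmax(seq_len(nc) - r, 0L); j1 <- pmin(seq_len(nc) + r, nc)
  S <- cs[i1 + 1L, j1 + 1L, drop = FALSE] - cs[i0 + 1L, j1 + 1L, drop = FALSE] -
       cs[i1 + 1L, j0 + 1L, drop = FALSE] + cs[i0 + 1L, j0 + 1L, drop = FALSE]
  cnt <- outer(i1 - i0, j1 - j0)
  S / cnt
}

standardize <- function(m) (m - mean(m)) / (stats::sd(m) + 1e-12)

#' Generate a synthetic two-epoch landscape
#'
#' Produces a clustered categorical map at epoch t0 (a smoothed Gaussian-type
#' field thresholded at the cumulative class fractions, so empirical
#' fractions match the requested ones), a second epoch t1 in which a
#' \code{changeFraction} share of cells transitions with per-class conversion
#' propensity logistic in \code{driverEffects \%*\% drivers}, the seven
#' standardized driver surfaces, and a red-line mask covering roughly 40\% of
#' cells built from a smoothed forest/water indicator.
#'
#' @param params a \code{\link{landscapeParams}} object.
#' @return list with elements \code{t0}, \code{t1} (\linkS4class{LandUseGrid}),
#'   \code{drivers} (\linkS4class{DriverStack}), \code{redline}
#'   (\linkS4class{RedLineMask}).
#' @export
generateLandscape <- function(params) {
  stopifnot(inherits(params, "LandscapeParams"))
  with_local_seed(params$seed, {
    nr <- params$rows; nc <- params$cols
    n <- nr * nc

    ## driver surfaces
    dem <- smooth_field(nr, nc)
    gy <- rbind(dem[2:nr, ] - dem[1:(nr - 1), ], 0)
    gx <- cbind(dem[, 2:nc] - dem[, 1:(nc - 1)], 0)
    slope <- sqrt(gx^2 + gy^2)
    drivers <- list(
      dem = dem,
      slope = standardize(slope),
      dist_rail = standardize(route_distance(nr, nc, 1L)),
      dist_road = standardize(route_distance(nr, nc, 3L)),
      dist_river = standardize(route_distance(nr, nc, 2L)),
      pop_density = standardize(exp(0.8 * smooth_field(nr, nc))),
      gdp = standardize(exp(0.8 * smooth_field(nr, nc))))
    stack <- DriverStack(drivers)

    ## epoch t0: threshold a smooth latent field at cumulative class fractions
    counts <- largest_remainder(params$classFractions * n, n)
    if (any(params$classFractions > 0 & counts == 0))
      stopf("infeasible classFractions for a %dx%d grid", nr, nc)
    latent <- smooth_field(nr, nc) + rnorm(n, sd = 1e-9)  # break ties
    ord <- order(latent)
    codes0 <- integer(n)
    codes0[ord] <- rep.int(1:.N_CLASSES, counts)
    codes0 <- matrix(codes0, nr, nc)

    ## epoch t1: logistic driver-dependent transitions
    Z <- vapply(drivers, as.vector, numeric(n))      # n x 7
    eta <- Z %*% t(params$driverEffects)             # n x 6
    q <- stats::plogis(eta)
    codes1 <- codes0
    n_change <- round(params$changeFraction * n)
    if (n_change > 0) {
      cur <- as.vector(codes0)
      qq <- q
      qq[cbind(seq_len(n), cur)] <- 0                # can't convert to self
      w <- rowSums(qq) / (.N_CLASSES - 1)
      chosen <- sample.int(n, n_change, prob = w)
      newk <- vapply(chosen, function(i)
        sample.int(.N_CLASSES, 1L, prob = qq[i, ]), integer(1))
      codes1[chosen] <- newk
    }

    ## red-line mask: smoothed forest/water indicator, top ~40% of cells
    eco <- (codes0 == 2L | codes0 == 4L) * 1
    sm <- box_blur(eco, r = max(3L, round(min(nr, nc) / 20)))
    thr <- quantile(sm, 0.6, names = FALSE)
    redline <- RedLineMask(sm >= thr)

    list(t0 = LandUseGrid(codes0, params$cellArea, epoch = "t0"),
         t1 = LandUseGrid(codes1, params$cellArea, epoch = "t1"),
         drivers = stack, redline = redline)
  })
}

#' Generate a synthetic consumption/productivity footprint table
#'
#' Consumption items per land type with per-capita consumption and national
#' mean productivity drawn from positive log-normal ranges; the equilibrium
#' factors are fixed at the published values (arable 1.74, grass 0.44,
#' forest 1.41, water 0.35).
#'
#' @param nItemsPerType number of consumption items per land type (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns \code{item}, \code{land_type},
#'   \code{consumption} (kg/cap), \code{productivity} (kg/hm2),
#'   \code{eq_factor}.
#' @export
generateFootprintTable <- function(nItemsPerType = 5L, seed = 1L) {
  stopifnot(nItemsPerType >= 1L)
  with_local_seed(seed, {
    types <- c(arable = 1.74, grass = 0.44, forest = 1.41, water = 0.35)
    rows <- lapply(names(types), function(tp) {
      data.frame(
        item = paste0(tp, "_item", seq_len(nItemsPerType)),
        land_type = tp,
        consumption = stats::rlnorm(nItemsPerType, log(50), 1),
        productivity = stats::rlnorm(nItemsPerType, log(500), 0.5),
        eq_factor = types[[tp]],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate short annual economic series per land class
#'
#' Each class value grows geometrically with multiplicative log-normal noise:
#' v_t = v_0 (1+growth)^t exp(noise * e_t). Used to exercise the GM(1,1)
#' grey forecaster on yearbook-like inputs.
#'
#' @param nYears number of annual observations (>= 4).
#' @param growth annual growth rate.
#' @param noise log-scale noise standard deviation (0 = deterministic).
#' @param seed RNG seed.
#' @param value0 numeric(6) initial values per class.
#' @param startYear first calendar year label.
#' @return data.frame with columns \code{year} and the six class labels.
#' @export
generateEconomicSeries <- function(nYears = 5L, growth = 0.08, noise = 0.05,
                                   seed = 1L,
                                   value0 = c(300, 12, 150, 200, 4e4, 6e4),
                                   startYear = 2000L) {
  stopifnot(nYears >= 4L, length(value0) == .N_CLASSES, all(value0 > 0))
  with_local_seed(seed, {
    t <- seq_len(nYears) - 1L
    out <- sapply(value0, function(v0) {
      base <- v0 * (1 + growth)^t
      if (noise > 0) base * exp(rnorm(nYears, 0, noise)) else base
    })
    colnames(out) <- .CLASS_LABELS
    data.frame(year = startYear + t, out, check.names = FALSE)
  })
}
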