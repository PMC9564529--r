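#' @include leas.R
NULL

#' Construct transition rules
#'
#' @param allowed 6x6 logical from->to permission matrix. The default allows
#'   all transitions among the four ecological classes and freezes the built
#'   classes in both directions (rows and columns 5-6 self-only), mirroring
#'   the practice of setting built-land transfer probability to zero.
#' @param frozenMask optional logical matrix of cells that never change
#'   (e.g. the arable-protection red line).
#' @return a \linkS4class{TransitionRules}.
#' @export
transitionRules <- function(allowed = defaultAllowedMatrix(),
                            frozenMask = NULL) {
  new("TransitionRules", allowed = allowed, frozenMask = frozenMask)
}

#' @rdname transitionRules
#' @export
defaultAllowedMatrix <- function() {
  al <- matrix(TRUE, .N_CLASSES, .N_CLASSES,
               dimnames = list(.CLASS_LABELS, .CLASS_LABELS))
  al[5L, -5L] <- FALSE; al[6L, -6L] <- FALSE
  al[-5L, 5L] <- FALSE; al[-6L, 6L] <- FALSE
  al
}

#' Construct CARS parameters
#'
#' @param patchThreshold per-class patch-generation threshold mu_k in [0,1]
#'   (scalar recycled to 6; default 0.5).
#' @param expansionCoefficient probability that a zero-neighborhood cell is
#'   considered for random patch seeding (default 0.1).
#' @param window odd neighborhood window size (default 3).
#' @param tauDecay decay factor of the competition threshold tau applied
#'   whenever an iteration changes no cells (default 0.5).
#' @param demandTolerance convergence tolerance in km2; NA means 0.1\% of the
#'   total landscape area.
#' @param maxIterations iteration cap (default 200).
#' @param seed RNG seed for roulette and seeding draws.
#' @return a \linkS4class{CarsParams}.
#' @export
carsParams <- function(patchThreshold = 0.5, expansionCoefficient = 0.1,
                       window = 3L, tauDecay = 0.5,
                       demandTolerance = NA_real_, maxIterations = 200L,
                       seed = 1L) {
  if (length(patchThreshold) == 1L)
    patchThreshold <- rep(patchThreshold, .N_CLASSES)
  new("CarsParams", patchThreshold = patchThreshold,
      expansionCoefficient = expansionCoefficient,
      window = as.integer(window), tauDecay = tauDecay,
      demandTolerance = demandTolerance,
      maxIterations = as.integer(maxIterations), seed = as.integer(seed))
}

# Sum of a matrix over window offsets (excluding the center), zero-padded.
shift_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    si <- max(1L, 1L - di):min(nr, nr - di)
    sj <- max(1L, 1L - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + m[si, sj]
  }
  out
}

#' Neighborhood effect of a class
#'
#' Omega(cell) = share of the surrounding window (center excluded) occupied
#' by class k; edge cells use the clipped window's valid-cell count as the
#' denominator, so Omega stays in [0, 1] everywhere. Nodata cells get NA.
#'
#' @param grid a \linkS4class{LandUseGrid}.
#' @param k class code 1..6.
#' @param window odd window size >= 3.
#' @return numeric matrix in [0, 1] (NA on nodata cells).
#' @export
neighborhoodEffect <- function(grid, k, window = 3L) {
  if (window < 3L || window %% 2L == 0L)
    stopf("window must be odd and >= 3")
  codes <- landCodes(grid)
  r <- (window - 1L) %/% 2L
  valid <- codes != .NODATA
  num <- shift_sum((codes == k & valid) * 1, r)
  den <- shift_sum(valid * 1, r)
  om <- ifelse(den > 0, num / den, 0)
  om[!valid] <- NA_real_
  om
}

#' Adaptive demand-driving coefficient update
#'
#' The per-class multiplier D_k tracks the gap G = demand - area between
#' iterations: if the absolute gap shrank (or the demand is met), D is left
#' unchanged; if it grew, D is scaled by the gap ratio G_now / G_prev --
#' taken in magnitude when the gap changed sign (overshoot) -- and clipped
#' to [0.1, 10] to keep the feedback bounded.
#'
#' @param dPrev previous coefficient.
#' @param demandK demanded area, km2.
#' @param areaNow,areaPrev current and previous areas, km2.
#' @return updated coefficient.
#' @export
adaptiveCoefficient <- function(dPrev, demandK, areaNow, areaPrev) {
  gNow <- demandK - areaNow
  gPrev <- demandK - areaPrev
  if (abs(gNow) <= abs(gPrev) || gNow == 0) return(dPrev)
  ratio <- if (gPrev == 0) 10 else abs(gNow / gPrev)
  min(10, max(0.1, dPrev * ratio))
}

as_prob_matrix <- function(p) {
  if (is(p, "ProbabilitySurface")) probSurface(p) else p
}

#' Overall conversion probability (competition branch)
#'
#' OP = P * Omega * D: growth probability times neighborhood effect times
#' the adaptive demand coefficient.
#'
#' @param P growth-probability matrix or \linkS4class{ProbabilitySurface}.
#' @param omega neighborhood-effect matrix.
#' @param D adaptive coefficient (scalar).
#' @return numeric matrix.
#' @export
overallProbability <- function(P, omega, D) {
  P <- as_prob_matrix(P)
  stopifnot(identical(dim(P), dim(omega)))
  P * omega * D
}

#' Overall conversion probability (random patch-seeding branch)
#'
#' On cells whose neighborhood effect is zero, a random draw r in (0,1) that
#' falls below the growth probability seeds a new patch with overall
#' probability OP = P * r * mu_k * D; other zero-neighborhood cells get 0.
#'
#' @param P growth-probability matrix or \linkS4class{ProbabilitySurface}.
#' @param r matrix of uniform draws, same shape.
#' @param mu patch-generation threshold mu_k.
#' @param D adaptive coefficient (scalar).
#' @return numeric matrix (zero where r >= P).
#' @export
overallProbabilitySeed <- function(P, r, mu, D) {
  P <- as_prob_matrix(P)
  stopifnot(identical(dim(P), dim(r)))
  ifelse(r < P, P * r * mu * D, 0)
}

# Vectorized roulette: for a weight matrix (rows = cells, cols = choices),
# draw one column per row with probability proportional to the weights.
# Rows with zero total weight return NA. Ties/zero handling is deterministic
# given the RNG stream.
roulette_pick <- function(W) {
  tot <- rowSums(W)
  pick <- rep(NA_integer_, nrow(W))
  ok <- tot > 0
  if (any(ok)) {
    cw <- W[ok, , drop = FALSE]
    cs <- t(apply(cw, 1, cumsum))
    u <- runif(sum(ok)) * tot[ok]
    pick[ok] <- max.col(cs >= u, ties.method = "first")
  }
  pick
}

#' Allocate a demand vector on the landscape
#'
#' Iterative patch-growing allocation. Each iteration computes, for every
#' class still in deficit, the overall probability surface (competition
#' branch P*Omega*D, seeding branch P*r*mu*D on zero-neighborhood cells that
#' pass the expansion-coefficient gate), lets the deficit classes compete
#' for convertible surplus-class cells by roulette wheel, and accepts
#' conversions whose overall probability clears the current threshold tau
#' (initialized at 1 and decayed by \code{tauDecay} whenever an iteration
#' changes no cell). Conversions are applied in decreasing overall
#' probability and capped so no class overshoots its target; when the
#' threshold bottoms out without convergence, surplus classes shed their
#' lowest-retention cells directly to the most probable deficit class.
#' Frozen cells and built-class cells never change; total cell count (hence
#' total area) is conserved exactly at every iteration.
#'
#' @param tBase base-year \linkS4class{LandUseGrid}.
#' @param probs list of 6 growth-probability surfaces (matrices or
#'   \linkS4class{ProbabilitySurface}s), indexed by class code.
#' @param demand \linkS4class{ScenarioDemand}, \linkS4class{AreaVector} or
#'   numeric(6) of demanded areas, km2; must total the landscape's valid
#'   area within the demand tolerance.
#' @param rules a \linkS4class{TransitionRules}.
#' @param params a \linkS4class{CarsParams}.
#' @return list with \code{grid} (the allocated \linkS4class{LandUseGrid}),
#'   \code{areaLog} (iterations x 6 matrix, km2), \code{iterations},
#'   \code{converged}, and \code{D} (final adaptive coefficients).
#' @export
allocateLand <- function(tBase, probs, demand, rules = transitionRules(),
                         params = carsParams()) {
  codes <- landCodes(tBase)
  ca <- cellArea(tBase)
  valid <- codes != .NODATA
  nValid <- sum(valid)
  dem <- if (is(demand, "ScenarioDemand")) areaKm2(demandAreas(demand))
         else if (is(demand, "AreaVector")) areaKm2(demand)
         else as.numeric(demand)
  stopifnot(length(dem) == .N_CLASSES)
  tol <- params@demandTolerance
  if (is.na(tol)) tol <- 0.001 * nValid * ca
  if (abs(sum(dem) - nValid * ca) > max(tol, ca))
    stopf("demand total %.2f km2 does not match landscape area %.2f km2",
          sum(dem), nValid * ca)
  P <- lapply(probs, as_prob_matrix)
  if (length(P) != .N_CLASSES) stopf("need 6 probability surfaces")
  frozen <- if (is.null(rules@frozenMask)) matrix(FALSE, nrow(codes), ncol(codes))
            else rules@frozenMask
  allowed <- rules@allowed

  target <- largest_remainder(dem / ca, nValid)
  counts <- tabulate(codes[valid], .N_CLASSES)

  ## reachability pre-check
  for (k in 1:.N_CLASSES) {
    if (target[k] > counts[k] && !any(allowed[-k, k]))
      stopf("demand requires growth of class %s but no transition into it is allowed",
            .CLASS_LABELS[k])
    if (target[k] < counts[k]) {
      leavers <- sum(codes == k & valid & !frozen)
      if (!any(allowed[k, -k]) || leavers < counts[k] - target[k])
        stopf("demand requires shrinking class %s by %d cells but only %d may leave",
              .CLASS_LABELS[k], counts[k] - target[k],
              if (any(allowed[k, -k])) leavers else 0L)
    }
  }

  with_local_seed(params@seed, {
    D <- rep(1, .N_CLASSES)
    tau <- 1
    areaLog <- matrix(NA_real_, 0, .N_CLASSES,
                      dimnames = list(NULL, .CLASS_LABELS))
    prevCounts <- counts
    converged <- FALSE
    iter <- 0L
    # built cells are immobilized through `allowed` rows 5-6 (self-only)
    mobile <- valid & !frozen
    while (iter < params@maxIterations) {
      iter <- iter + 1L
      counts <- tabulate(codes[valid], .N_CLASSES)
      areaLog <- rbind(areaLog, counts * ca)
      diffs <- target - counts
      # stop at the integer cell targets or once every class is within the
      # demand tolerance of the (fractional) demanded area
      if (all(diffs == 0L) || all(abs(dem - counts * ca) <= tol)) {
        converged <- TRUE; break
      }

      for (k in 1:.N_CLASSES)
        D[k] <- adaptiveCoefficient(D[k], target[k] * ca, counts[k] * ca,
                                    prevCounts[k] * ca)
      prevCounts <- counts

      deficit <- which(diffs > 0)
      surplus <- which(diffs < 0)
      grid_now <- LandUseGrid(codes, ca)

      ## overall probability per deficit class
      OP <- vector("list", .N_CLASSES)
      for (k in deficit) {
        om <- neighborhoodEffect(grid_now, k, params@window)
        op <- overallProbability(P[[k]], ifelse(is.na(om), 0, om), D[k])
        zero_nb <- !is.na(om) & om == 0
        if (any(zero_nb) && params@expansionCoefficient > 0) {
          gate <- matrix(runif(length(codes)) < params@expansionCoefficient,
                         nrow(codes), ncol(codes))
          rmat <- matrix(runif(length(codes)), nrow(codes), ncol(codes))
          seeded <- overallProbabilitySeed(P[[k]], rmat,
                                           params@patchThreshold[k], D[k])
          op[zero_nb & gate] <- seeded[zero_nb & gate]
        }
        OP[[k]] <- op
      }

      ## roulette competition on convertible surplus cells
      changed <- 0L
      cand <- which(mobile & matrix(codes %in% surplus, nrow(codes)))
      if (length(cand) && length(deficit)) {
        from <- codes[cand]
        W <- vapply(deficit, function(k) {
          w <- OP[[k]][cand]
          w[!allowed[cbind(from, k)]] <- 0
          w[is.na(w)] <- 0
          w
        }, numeric(length(cand)))
        if (is.null(dim(W))) W <- matrix(W, nrow = length(cand))
        pick <- roulette_pick(W)
        sel <- which(!is.na(pick))
        if (length(sel)) {
          opv <- W[cbind(sel, pick[sel])]
          keep <- opv >= tau
          sel <- sel[keep]; opv <- opv[keep]
          ord <- order(opv, decreasing = TRUE)
          for (idx in ord) {
            i <- cand[sel[idx]]
            k <- deficit[pick[sel[idx]]]
            j <- codes[i]
            if (diffs[k] > 0 && diffs[j] < 0) {
              codes[i] <- k
              diffs[k] <- diffs[k] - 1L
              diffs[j] <- diffs[j] + 1L
              changed <- changed + 1L
            }
          }
        }
      }

      if (changed == 0L) {
        tau <- tau * params@tauDecay
        if (tau < 1e-8) {
          ## deterministic shedding: surplus classes release their
          ## lowest-retention cells to the most probable deficit class
          moved <- 0L
          for (j in surplus) {
            need_out <- -diffs[j]
            if (need_out <= 0) next
            cells_j <- which(mobile & codes == j)
            if (!length(cells_j)) next
            ret <- P[[j]][cells_j]
            ret[is.na(ret)] <- 0
            cells_j <- cells_j[order(ret)]
            for (i in cells_j) {
              if (diffs[j] >= 0) break
              opts <- deficit[allowed[j, deficit] & diffs[deficit] > 0]
              if (!length(opts)) break
              sc <- vapply(opts, function(k) {
                v <- OP[[k]][i]
                if (is.null(v) || is.na(v)) 0 else v
              }, numeric(1))
              pb <- vapply(opts, function(k) {
                v <- P[[k]][i]
                if (is.na(v)) 0 else v
              }, numeric(1))
              k <- opts[order(-sc, -pb, opts)[1]]
              codes[i] <- k
              diffs[k] <- diffs[k] - 1L
              diffs[j] <- diffs[j] + 1L
              moved <- moved + 1L
            }
          }
          if (moved == 0L)
            stopf("allocation stalled: demand for class %s is unreachable under the transition rules",
                  .CLASS_LABELS[deficit[1]])
          tau <- 1
        }
      }
    }
    if (!converged) {
      counts <- tabulate(codes[valid], .N_CLASSES)
      areaLog <- rbind(areaLog, counts * ca)
      converged <- all(target == counts) || all(abs(dem - counts * ca) <= tol)
    }
    list(grid = LandUseGrid(codes, ca, classLabels(tBase), "allocated"),
         areaLog = areaLog, iterations = iter, converged = converged, D = D)
  })
}

#' Run one scenario end to end on a landscape
#'
#' Composes the land-expansion analysis (fit on the t0 -> t1 transition) with
#' the patch-growing allocation of the scenario demand on the later epoch.
#' One expansion fit can be shared across scenarios by passing
#' \code{probs} explicitly.
#'
#' @param t0,t1 the two calibration epochs (\linkS4class{LandUseGrid}).
#' @param drivers a \linkS4class{DriverStack}.
#' @param demand demanded areas (see \code{\link{allocateLand}}).
#' @param rules a \linkS4class{TransitionRules}.
#' @param params a \linkS4class{CarsParams}.
#' @param probs optional precomputed list of 6 probability surfaces; when
#'   NULL they are fitted here via \code{\link{leasProbabilities}}.
#' @param M,nPerClass expansion-model settings when \code{probs} is NULL.
#' @return list with \code{grid}, \code{diagnostics} (final
#'   \linkS4class{AreaVector}, iterations, converged flag, kappa vs the base
#'   epoch) and \code{probs}.
#' @export
runScenario <- function(t0, t1, drivers, demand, rules = transitionRules(),
                        params = carsParams(), probs = NULL, M = 50L,
                        nPerClass = 2000L) {
  if (is.null(probs)) {
    fit <- leasProbabilities(t0, t1, drivers, M = M, nPerClass = nPerClass,
                             seed = params@seed, onEmpty = "zero")
    probs <- fit$probs
  }
  res <- allocateLand(t1, probs, demand, rules, params)
  diag <- list(areas = classAreas(res$grid), iterations = res$iterations,
               converged = res$converged,
               kappaVsBase = kappaAgreement(res$grid, t1))
  list(grid = res$grid, diagnostics = diag, probs = probs,
       areaLog = res$areaLog)
}
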