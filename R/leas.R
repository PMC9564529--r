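#' @include mop-optimizer.R
NULL

#' Extract per-class expansion between two epochs
#'
#' A cell is a positive (1) for class k when it was not k at the first epoch
#' and is k at the second; cells already k at the first epoch are excluded
#' from both positives and eligible negatives (NA), and the remaining valid
#' cells are eligible negatives (0). Nodata in either epoch is NA.
#'
#' @param t0,t1 comparable \linkS4class{LandUseGrid}s.
#' @param k class code 1..6.
#' @return integer matrix in \{1, 0, NA\} with attribute \code{landClass}.
#' @export
extractExpansion <- function(t0, t1, k) {
  checkComparable(t0, t1)
  stopifnot(k >= 1, k <= .N_CLASSES)
  c0 <- landCodes(t0); c1 <- landCodes(t1)
  valid <- c0 != .NODATA & c1 != .NODATA
  out <- matrix(NA_integer_, nrow(c0), ncol(c0))
  eligible <- valid & c0 != k
  out[eligible] <- 0L
  out[eligible & c1 == k] <- 1L
  attr(out, "landClass") <- as.integer(k)
  out
}

#' Draw training samples from an expansion map
#'
#' \code{balanced} (the default) draws equal numbers of positives and
#' negatives without replacement, capped by availability and by half the
#' requested size; \code{uniform} draws cells uniformly from all eligible
#' cells so label frequencies mirror the map. Sampling is deterministic
#' under \code{seed}.
#'
#' @param expansion expansion map from \code{\link{extractExpansion}}.
#' @param drivers a \linkS4class{DriverStack} on the same grid.
#' @param nPerClass total requested sample size (default 5000).
#' @param strategy "balanced" or "uniform".
#' @param seed RNG seed.
#' @return data.frame with columns \code{cell}, \code{label} (factor 0/1)
#'   and one column per driver.
#' @export
sampleTraining <- function(expansion, drivers, nPerClass = 5000L,
                           strategy = c("balanced", "uniform"), seed = 1L) {
  strategy <- match.arg(strategy)
  k <- attr(expansion, "landClass")
  pos <- which(expansion == 1L)
  neg <- which(expansion == 0L)
  if (!length(pos))
    stopf("no expansion cells for class %s",
          if (is.null(k)) "?" else .CLASS_LABELS[k])
  with_local_seed(seed, {
    if (strategy == "balanced") {
      npos <- min(length(pos), floor(nPerClass / 2))
      nneg <- min(length(neg), npos)
      take_pos <- if (npos < length(pos)) sample(pos, npos) else pos
      take_neg <- if (nneg < length(neg)) sample(neg, nneg) else neg
      cells <- c(take_pos, take_neg)
    } else {
      all_cells <- c(pos, neg)
      n <- min(nPerClass, length(all_cells))
      cells <- sample(all_cells, n)
    }
    X <- vapply(surfaces(drivers), function(s) s[cells],
                numeric(length(cells)))
    if (is.null(dim(X))) X <- matrix(X, nrow = length(cells))
    colnames(X) <- driverNames(drivers)
    df <- data.frame(cell = cells,
                     label = factor(expansion[cells], levels = c(0, 1)),
                     X, check.names = FALSE)
    attr(df, "landClass") <- k
    df
  })
}

#' Fit a per-class growth ensemble
#'
#' One-vs-rest classification forest of M trees on the driver values;
#' \code{mtry} is the conventional floor(sqrt(p)). Its prediction at a cell
#' is the fraction of trees voting that other classes convert to this class
#' there (the vote ratio over the ensemble).
#'
#' @param samples training frame from \code{\link{sampleTraining}}.
#' @param M number of trees (default 50).
#' @param seed RNG seed for the forest's bootstrap and split draws.
#' @return a \linkS4class{GrowthModel}.
#' @export
fitGrowthModel <- function(samples, M = 50L, seed = 1L) {
  drv <- setdiff(names(samples), c("cell", "label"))
  if (nlevels(droplevels(samples$label)) < 2L)
    stopf("training samples contain a single label; need both 0 and 1")
  with_local_seed(seed, {
    rf <- randomForest::randomForest(
      x = samples[, drv, drop = FALSE], y = samples$label,
      ntree = M, mtry = max(1L, floor(sqrt(length(drv)))),
      importance = FALSE)
    k <- attr(samples, "landClass")
    new("GrowthModel", landClass = if (is.null(k)) 1L else k,
        ntree = as.integer(M), forest = rf, driverNames = drv)
  })
}

#' Growth-probability surface of a class
#'
#' Evaluates the fitted ensemble at every cell of the driver stack; the
#' value is (trees voting for conversion) / M, in [0, 1].
#'
#' @param model a \linkS4class{GrowthModel}.
#' @param drivers a \linkS4class{DriverStack} containing every driver the
#'   model was trained on.
#' @return a \linkS4class{ProbabilitySurface}.
#' @export
growthProbability <- function(model, drivers) {
  missing <- setdiff(model@driverNames, driverNames(drivers))
  if (length(missing))
    stopf("driver(s) missing from stack: %s", paste(missing, collapse = ", "))
  s <- surfaces(drivers)
  d <- dim(s[[1]])
  newdata <- as.data.frame(lapply(s[model@driverNames], as.vector))
  names(newdata) <- model@driverNames
  votes <- predict(model@forest, newdata, type = "vote")  # normalized votes
  P <- matrix(votes[, "1"], d[1], d[2])
  new("ProbabilitySurface", prob = P, landClass = model@landClass)
}

#' Driver and needs-group importance of a growth model
#'
#' Impurity (Gini) importances normalized to sum one, and their aggregation
#' into the security/spiritual/material needs groups. A driver assigned to g
#' groups contributes 1/g of its importance to each (population density and
#' slope sit in two groups under the default assignment).
#'
#' @param model a \linkS4class{GrowthModel}.
#' @param groups named list driver -> group vector; defaults to the standard
#'   grouping of the canonical drivers.
#' @return list with \code{driver} (named numeric, sums to 1) and
#'   \code{group} (named numeric over the three groups, sums to 1).
#' @export
driverImportance <- function(model,
                             groups = defaultNeedsGroups(model@driverNames)) {
  imp <- randomForest::importance(model@forest, type = 2)[, 1]
  imp <- imp[model@driverNames]
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else
    setNames(rep(1 / length(imp), length(imp)), names(imp))
  grp <- c(security = 0, spiritual = 0, material = 0)
  for (d in names(imp)) {
    g <- groups[[d]]
    grp[g] <- grp[g] + imp[[d]] / length(g)
  }
  list(driver = imp, group = grp)
}

#' Fit growth models and probability surfaces for every class
#'
#' One land-expansion analysis pass: per class, extract the expansion map
#' between the two epochs, sample training cells, fit the ensemble and
#' evaluate its probability surface. Classes that never expanded either
#' raise an error (default) or receive an all-zero surface
#' (\code{onEmpty = "zero"}), which allocation treats as "cannot grow".
#'
#' @param t0,t1 comparable \linkS4class{LandUseGrid}s.
#' @param drivers a \linkS4class{DriverStack}.
#' @param classes class codes to fit (default all six).
#' @param M trees per ensemble.
#' @param nPerClass training sample cap per class.
#' @param seed RNG seed (per-class seeds are derived deterministically).
#' @param onEmpty "error" or "zero" for classes with no expansion cells.
#' @return list with \code{models} and \code{probs}, each indexed 1..6.
#' @export
leasProbabilities <- function(t0, t1, drivers, classes = 1:.N_CLASSES,
                              M = 50L, nPerClass = 5000L, seed = 1L,
                              onEmpty = c("error", "zero")) {
  onEmpty <- match.arg(onEmpty)
  models <- vector("list", .N_CLASSES)
  probs <- vector("list", .N_CLASSES)
  d <- dim(landCodes(t0))
  for (k in classes) {
    exp_k <- extractExpansion(t0, t1, k)
    if (!any(exp_k == 1L, na.rm = TRUE)) {
      if (onEmpty == "error")
        stopf("no expansion cells for class %s", .CLASS_LABELS[k])
      probs[[k]] <- new("ProbabilitySurface",
                        prob = matrix(0, d[1], d[2]),
                        landClass = as.integer(k))
      next
    }
    smp <- sampleTraining(exp_k, drivers, nPerClass, "balanced",
                          seed = seed + 1000L * k)
    models[[k]] <- fitGrowthModel(smp, M = M, seed = seed + 1000L * k + 1L)
    probs[[k]] <- growthProbability(models[[k]], drivers)
  }
  list(models = models, probs = probs)
}
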