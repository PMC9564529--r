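#' @include needs-models.R
NULL

#' Fit a GM(1,1) grey forecasting model
#'
#' Standard single-variable grey model: the raw series x0 is accumulated
#' once (x1(k) = sum of x0(1..k)), trapezoidal background values
#' z(k) = (x1(k) + x1(k-1)) / 2 are formed, and the development coefficient a
#' and grey input b are estimated by least squares in
#' x0(k) + a z(k) = b for k = 2..n. The model is exact on exponential trends
#' up to an O(a^3) bias in a induced by the trapezoidal background.
#'
#' @param series positive numeric series, length >= 4.
#' @return a \linkS4class{GreyModel}.
#' @export
gm11Fit <- function(series) {
  x0 <- as.numeric(series)
  if (length(x0) < 4L) stopf("GM(1,1) needs >= 4 observations")
  if (any(!is.finite(x0)) || any(x0 <= 0))
    stopf("GM(1,1) requires strictly positive observations")
  n <- length(x0)
  x1 <- cumsum(x0)
  z <- (x1[-1] + x1[-n]) / 2
  y <- x0[-1]
  # least squares for (a, b) in y = -a z + b
  zc <- z - mean(z)
  den <- sum(zc^2)
  if (den < 1e-12 * mean(z)^2) {
    # accumulated series linear in k: constant raw series, a = 0
    a <- 0
    b <- mean(y)
  } else {
    a <- -sum(zc * (y - mean(y))) / den
    b <- mean(y) + a * mean(z)
  }
  new("GreyModel", a = a, b = b, x0First = x0[1], n = as.integer(n))
}

#' Forecast from a fitted GM(1,1) model
#'
#' The time-response restoration
#' x0hat(k) = (x0(1) - b/a) (1 - e^a) e^{-a (k - 1)} for k >= 2 is evaluated
#' at k = n+1, ..., n+horizon. When a = 0 (stationary series) forecasts are
#' the constant b.
#'
#' @param model a \linkS4class{GreyModel}.
#' @param horizon number of steps ahead (0 gives an empty vector).
#' @return numeric vector of length \code{horizon}.
#' @export
gm11Forecast <- function(model, horizon) {
  stopifnot(is(model, "GreyModel"), horizon >= 0)
  if (horizon == 0) return(numeric(0))
  k <- model@n + seq_len(horizon)
  if (model@a == 0) return(rep(model@b, horizon))
  (model@x0First - model@b / model@a) * (1 - exp(model@a)) *
    exp(-model@a * (k - 1))
}

#' Linear-development (LD) projection of class areas
#'
#' Per class, an ordinary least-squares line through the historical areas is
#' evaluated at the target year; negative extrapolations are floored at zero
#' and the six classes are then rescaled proportionally so the total equals
#' the fixed regional area. This is the no-intervention baseline scenario.
#'
#' @param areaSeries matrix or data.frame of historical areas, one column per
#'   class (canonical order), one row per observation year.
#' @param years numeric vector of observation years (>= 2 distinct).
#' @param targetYear year to project to.
#' @param regionTotalS total to close the projection to, km2.
#' @return a \linkS4class{ScenarioDemand} with scenario "LD".
#' @export
linearProjection <- function(areaSeries, years, targetYear = 2035,
                             regionTotalS = 33481.23) {
  m <- as.matrix(areaSeries)
  stopifnot(ncol(m) == .N_CLASSES, nrow(m) == length(years))
  if (length(unique(years)) < 2L) stopf("need >= 2 distinct years")
  raw <- apply(m, 2, function(a) {
    fit <- lm(a ~ years)
    unname(predict(fit, data.frame(years = targetYear)))
  })
  raw <- pmax(raw, 0)
  tot <- sum(raw)
  if (tot <= 0) stopf("projection collapsed to zero total area")
  scaled <- raw * regionTotalS / tot
  new("ScenarioDemand", scenario = "LD", areas = AreaVector(scaled),
      objectiveValue = NA_real_, status = "optimal")
}
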