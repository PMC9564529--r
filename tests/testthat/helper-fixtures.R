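# Shared fixture builders; everything is generated in code.

# Equal class fractions keep small grids feasible.
small_params <- function(rows = 40L, cols = 40L, seed = 1L,
                         changeFraction = 0.1,
                         driverEffects = defaultDriverEffects()) {
  landscapeParams(rows = rows, cols = cols,
                  classFractions = rep(1 / 6, 6),
                  driverEffects = driverEffects,
                  changeFraction = changeFraction, seed = seed)
}

# A tiny grid from explicit codes (row-major input for readability).
grid_from <- function(v, nrow, cellArea = 1, epoch = "") {
  LandUseGrid(matrix(as.integer(v), nrow = nrow, byrow = TRUE),
              cellArea = cellArea, epoch = epoch)
}

# Driver effects with one dominant driver (3x the rest) for class k.
dominant_effects <- function(k, driver = "dem", factor = 3) {
  W <- matrix(1, 6, 7, dimnames = dimnames(defaultDriverEffects()))
  W[k, driver] <- factor
  W
}

# Uniform positive probability surfaces for allocation tests.
flat_probs <- function(d, p = 0.5) {
  lapply(1:6, function(k)
    new("ProbabilitySurface", prob = matrix(p, d[1], d[2]),
        landClass = as.integer(k)))
}

# Mann-Whitney AUC of scores for positives vs negatives.
auc_of <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
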