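# Exhaustive vertex-enumeration LP oracle, independent of the simplex path.
# Constraints: rows of A with direction in {"<=", ">=", "="} against b, plus
# implicit x >= 0. Every vertex of the polytope is the solution of n active
# constraints; enumerate all n-subsets (equalities always active), keep the
# feasible ones, and take the best objective value.
vertex_enum_lp <- function(obj, A, dir, b, maximize = TRUE, tol = 1e-7) {
  n <- length(obj)
  A_all <- rbind(A, diag(n))              # nonnegativity rows appended
  dir_all <- c(dir, rep(">=", n))
  b_all <- c(b, rep(0, n))
  m <- nrow(A_all)
  eq <- which(dir_all == "=")
  free <- setdiff(seq_len(m), eq)
  pick <- utils::combn(free, n - length(eq))
  best <- -Inf * if (maximize) 1 else -1
  best_x <- NULL
  for (j in seq_len(ncol(pick))) {
    act <- c(eq, pick[, j])
    M <- A_all[act, , drop = FALSE]
    x <- tryCatch(solve(M, b_all[act]), error = function(e) NULL)
    if (is.null(x)) next
    lhs <- as.vector(A_all %*% x)
    feas <- all(ifelse(dir_all == "<=", lhs <= b_all + tol,
                ifelse(dir_all == ">=", lhs >= b_all - tol,
                       abs(lhs - b_all) <= tol)))
    if (!feas) next
    v <- sum(obj * x)
    if ((maximize && v > best) || (!maximize && v < best)) {
      best <- v; best_x <- x
    }
  }
  list(value = best, x = best_x)
}

# Random bounded, feasible 6-variable LP: a box plus a few extra <= rows
# anchored at an interior point.
random_lp <- function(n_extra = 3L) {
  n <- 6L
  u <- runif(n, 1, 10)
  x0 <- runif(n, 0.1, 0.9) * u
  A <- diag(n); dir <- rep("<=", n); b <- u
  for (i in seq_len(n_extra)) {
    a <- runif(n)
    A <- rbind(A, a); dir <- c(dir, "<="); b <- c(b, sum(a * x0) + runif(1, 0.5, 2))
  }
  obj <- runif(n, -1, 1)
  list(objective = obj, A = A, dir = dir, b = b)
}

# Adapt a direction-form LP to the solveLp() interface.
as_lp_desc <- function(rlp, scenario = "security") {
  le <- rlp$dir == "<="; ge <- rlp$dir == ">="; eq <- rlp$dir == "="
  list(objective = rlp$objective,
       A1 = if (any(le)) rlp$A[le, , drop = FALSE] else NULL,
       b1 = if (any(le)) rlp$b[le] else NULL,
       A2 = if (any(ge)) rlp$A[ge, , drop = FALSE] else NULL,
       b2 = if (any(ge)) rlp$b[ge] else NULL,
       A3 = if (any(eq)) rlp$A[eq, , drop = FALSE] else NULL,
       b3 = if (any(eq)) rlp$b[eq] else NULL,
       scenario = scenario)
}

# The package constraint set in direction form, for oracle cross-checks.
hechi_dir_form <- function(cs = constraintSet()) {
  e <- function(i) replace(numeric(6), i, 1)
  pop <- 120 * (e(1) + e(2) + e(3)) + 3000 * (e(5) + e(6))
  foot <- e(1) + e(2) + e(3) + e(4)
  A <- rbind(rep(1, 6), pop, pop, e(1), e(5), e(5), e(4), foot, foot)
  dir <- c("=", "<=", ">=", ">=", "<=", ">=", ">=", "<=", ">=")
  b <- c(cs@totalArea, cs@popHigh, cs@popLow, cs@arableMin, cs@builtHigh,
         cs@builtLow, cs@waterMin, cs@footprintHigh, cs@footprintLow)
  list(A = A, dir = dir, b = b)
}
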