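# Internal helpers shared across modules.

#' @importFrom stats runif rnorm quantile coef lm predict setNames
#' @importFrom utils read.csv write.csv head
NULL

# Canonical class ordering used by every area vector and matrix in the package.
.CLASS_LABELS <- c("arable", "forest", "grass", "water",
                   "residential", "industrial")
.N_CLASSES <- 6L
.NODATA <- -1L

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Largest-remainder rounding: integer vector summing exactly to round(sum(x)).
largest_remainder <- function(x, total = NULL) {
  if (is.null(total)) total <- round(sum(x))
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - fl)
    k <- seq_len(-rem)
    fl[ord[k]] <- fl[ord[k]] - 1
  }
  as.integer(fl)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
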