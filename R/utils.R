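# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic derived seed below 2^31 from a base seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Symmetric matrix square root and inverse square root via eigendecomposition.
mat_sqrt <- function(S, inverse = FALSE, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  d <- if (inverse) 1 / sqrt(vals) else sqrt(vals)
  e$vectors %*% (d * t(e$vectors))
}

# Centered moving-average (rectangular) smoother, edge-padded; cumsum
# implementation for O(n) cost.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  pad <- n %/% 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], n - 1 - pad))
  cs <- cumsum(xp)
  (cs[n:length(xp)] - c(0, cs[seq_len(length(xp) - n)])) / n
}

# Contiguous runs of TRUE in a logical vector -> matrix of (start, end).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- rlang::`%||%`
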