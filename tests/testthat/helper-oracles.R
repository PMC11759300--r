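# Independent brute-force oracles and small fixture builders.

# O(M^3) natural-visibility construction straight from the defining
# inequality: x < y connected iff every intermediate z lies strictly
# below the chord.
vg_brute_force <- function(v) {
  m <- length(v)
  adj <- matrix(0L, m, m)
  for (x in seq_len(m - 1L)) {
    for (y in (x + 1L):m) {
      visible <- TRUE
      if (y > x + 1L) {
        for (z in (x + 1L):(y - 1L)) {
          chord <- v[x] + (v[y] - v[x]) * (z - x) / (y - x)
          if (v[z] >= chord) { visible <- FALSE; break }
        }
      }
      if (visible) adj[x, y] <- adj[y, x] <- 1L
    }
  }
  adj
}

# Floyd-Warshall global efficiency with 1/weight edge lengths.
ge_floyd_warshall <- function(layer) {
  d <- ifelse(layer > 0, 1 / layer, Inf)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# Weighted Pearson correlation of endpoint strengths via stats::cov.wt.
assortativity_covwt <- function(layer) {
  s <- rowSums(layer)
  ut <- which(upper.tri(layer) & layer > 0, arr.ind = TRUE)
  if (nrow(ut) < 2L) return(NA_real_)
  w <- layer[ut]
  df <- cbind(c(s[ut[, 1]], s[ut[, 2]]), c(s[ut[, 2]], s[ut[, 1]]))
  cw <- stats::cov.wt(df, wt = c(w, w), cor = TRUE, method = "ML")
  if (any(diag(cw$cov) <= 1e-12 * max(df^2, 1))) return(NA_real_)
  cw$cor[1, 2]
}

# Random non-negative symmetric 6-node layer (some zero edges).
random_layer <- function(seed, p_zero = 0.3) {
  set.seed(seed)
  m <- matrix(0, 6, 6)
  w <- runif(15)
  w[runif(15) < p_zero] <- 0
  m[upper.tri(m)] <- w
  m <- m + t(m)
  dimnames(m) <- list(MN_CHANNELS, MN_CHANNELS)
  m
}

# Pure-sinusoid distance series fixture.
sinusoid_trace <- function(f, amplitude = 5, duration = 10, fs = 100,
                           base = 30) {
  t <- seq(0, duration, by = 1 / fs)
  d <- base + amplitude * sin(2 * pi * f * t)
  u <- c(0, 0, -1)
  jaw_trace(t, outer(d, u), fs = fs, reference = c(0, 0, 0))
}

# Six-channel recording with two channels mixed by a known instantaneous
# matrix, the rest independent.
mixed_pair_recording <- function(seed, mix = 0.3, fs = 2000, duration = 4) {
  set.seed(seed)
  n <- duration * fs
  bp <- function(b) {
    z <- signal::filtfilt(signal::butter(4, b / (fs / 2), type = "pass"),
                          rnorm(n + 2 * fs))[(fs + 1):(fs + n)]
    z / sd(z)
  }
  s1 <- bp(c(60, 200)); s2 <- bp(c(150, 450))
  x <- rbind(s1 + mix * s2, bp(c(80, 300)), s2 + mix * s1,
             bp(c(100, 350)), bp(c(70, 250)), bp(c(120, 400)))
  semg_recording(x, fs = fs)
}

# Pure-noise feature tibble.
with_seed_matrix <- function(seed, n, p) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  tibble::as_tibble(x)
}

# Factor-score records for two groups with a known separation.
scored_groups <- function(seed, n_sub = 20, n_rec = 8, delta = 2, k = 4) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_sub)), each = n_rec)
  grp <- rep(rep(c("ALS", "control"), each = n_sub / 2), each = n_rec)
  f <- matrix(rnorm(n_sub * n_rec * k), ncol = k)
  f[grp == "ALS", 1] <- f[grp == "ALS", 1] + delta
  colnames(f) <- paste0("factor", seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = subj, group = grp),
                   tibble::as_tibble(f))
}
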