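# Nodal features: visibility-graph descriptors of each muscle's activity.
#
# Each preprocessed sEMG channel is reduced to a local standard deviation
# series (non-overlapping windows), mapped to a natural visibility graph,
# and summarized by two descriptors: graph density (overall level of
# activity) and spectral radius ratio (variability of activity).

#' Local standard deviation series of a signal
#'
#' Splits a signal into consecutive non-overlapping blocks of `window_len`
#' samples and returns the sample standard deviation (denominator `L - 1`)
#' of each block. A trailing remainder shorter than one block is dropped.
#' At 2,000 Hz the default window of 100 samples spans 50 ms.
#'
#' @param signal Numeric vector.
#' @param window_len Block length `L` in samples (>= 2).
#' @param source_channel Optional channel label carried along for reporting.
#' @return An object of class `local_sd_series`: list with `values`
#'   (length `floor(N / L)`), `window_len` and `source_channel`.
#' @export
local_sd_series <- function(signal, window_len = 100L, source_channel = NA_character_) {
  L <- as.integer(window_len)
  n <- length(signal)
  if (L < 2L) abort("`window_len` must be at least 2 samples.")
  if (n < L) abort(sprintf("signal has %d samples, shorter than one window (L = %d).", n, L))
  m <- n %/% L
  blocks <- matrix(signal[seq_len(m * L)], nrow = L)
  mu <- colMeans(blocks)
  v <- sqrt(colSums((blocks - rep(mu, each = L))^2) / (L - 1))
  structure(
    list(values = v, window_len = L, source_channel = source_channel),
    class = "local_sd_series"
  )
}

series_values <- function(series) {
  if (inherits(series, "local_sd_series")) series$values else as.numeric(series)
}

#' Natural visibility graph of a series
#'
#' Treats each point of the series as a node; nodes `x < y` are connected
#' when every intermediate point `z` lies strictly below the straight line
#' from `(x, V_x)` to `(y, V_y)`, i.e.
#' `(V_y - V_z) / (y - z) > (V_y - V_x) / (y - x)` for all `x < z < y`.
#' The inequality is strict, so a collinear intermediate point blocks
#' visibility. Adjacent points are always connected (vacuous condition).
#'
#' @param series A `local_sd_series` or numeric vector (>= 2 points).
#' @return An object of class `visibility_graph`: list with a symmetric 0/1
#'   `adjacency` matrix and `n_nodes`.
#' @export
visibility_graph <- function(series) {
  v <- series_values(series)
  m <- length(v)
  if (m < 2L) abort("visibility graph needs at least 2 points.")
  adj <- matrix(0L, m, m)
  for (x in seq_len(m - 1L)) {
    slopes <- (v[(x + 1L):m] - v[x]) / seq_len(m - x)
    k <- length(slopes)
    vis <- if (k == 1L) TRUE else c(TRUE, slopes[-1L] > cummax(slopes)[-k])
    adj[x, (x + 1L):m][vis] <- 1L
  }
  adj <- adj + t(adj)
  structure(list(adjacency = adj, n_nodes = m), class = "visibility_graph")
}

graph_adjacency <- function(g) {
  if (inherits(g, "visibility_graph")) g$adjacency else as.matrix(g)
}

#' Density of a visibility graph
#'
#' Ratio of the number of edges to the largest possible number of edges,
#' `2 m / (M (M - 1))`.
#'
#' @param g A `visibility_graph` (or adjacency matrix), `M >= 2` nodes.
#' @return Density in `(0, 1]`.
#' @export
graph_density <- function(g) {
  adj <- graph_adjacency(g)
  m_nodes <- nrow(adj)
  if (m_nodes < 2L) abort("density is undefined for fewer than 2 nodes.")
  n_edges <- sum(adj) / 2
  2 * n_edges / (m_nodes * (m_nodes - 1))
}

#' Spectral radius ratio of a visibility graph
#'
#' Principal eigenvalue of the 0/1 adjacency matrix divided by the mean
#' node degree. Always >= 1 (Rayleigh-quotient bound); equals 1 for a
#' regular graph, larger for heterogeneous (hub-dominated) connectivity.
#'
#' @param g A `visibility_graph` (or adjacency matrix) with >= 1 edge.
#' @return Ratio >= 1.
#' @export
spectral_radius_ratio <- function(g) {
  adj <- graph_adjacency(g)
  deg <- rowSums(adj)
  if (sum(deg) == 0) abort("spectral radius ratio is undefined for an edgeless graph.")
  lambda <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values[1]
  lambda / mean(deg)
}

#' Nodal feature vector of a six-channel recording
#'
#' Computes visibility-graph density and spectral radius ratio for each of
#' the six muscles from a (preprocessed) recording: 12 named features.
#'
#' @param rec A `semg_recording` (see [semg_recording()]), ideally after
#'   [preprocess_semg()].
#' @param window_len Local-SD window in samples (default 100, i.e. 50 ms at
#'   2,000 Hz).
#' @return A one-row tibble with columns `density_<CH>` and
#'   `specradRatio_<CH>` for the six channels.
#' @export
nodal_features <- function(rec, window_len = 100L) {
  rec <- as_semg_recording(rec)
  vals <- lapply(seq_len(6L), function(i) {
    ch <- rec$channel_labels[i]
    res <- tryCatch({
      g <- visibility_graph(local_sd_series(rec$samples[i, ], window_len, ch))
      c(density = graph_density(g), specradRatio = spectral_radius_ratio(g))
    }, error = function(e) {
      abort(sprintf("nodal features failed for channel %s: %s", ch, conditionMessage(e)))
    })
    res
  })
  out <- c(
    vapply(vals, `[[`, numeric(1), "density"),
    vapply(vals, `[[`, numeric(1), "specradRatio")
  )
  names(out) <- c(paste0("density_", rec$channel_labels),
                  paste0("specradRatio_", rec$channel_labels))
  tibble::as_tibble_row(as.list(out))
}
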