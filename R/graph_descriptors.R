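# Edgewise descriptors of the multiplex network: mean nodal strength,
# assortativity, global efficiency, weighted clustering, laterality.

layer_matrix <- function(layer) {
  m <- as.matrix(layer)
  stopifnot(nrow(m) == 6L, ncol(m) == 6L)
  diag(m) <- 0
  m
}

#' Mean nodal strength of a band layer
#'
#' Average over nodes of summed incident edge weights,
#' `2 * sum(weights) / 6`; the overall functional connectivity of the
#' layer.
#'
#' @param layer 6 x 6 symmetric non-negative weight matrix.
#' @return Value >= 0.
#' @export
mean_nodal_strength <- function(layer) {
  m <- layer_matrix(layer)
  mean(rowSums(m))
}

#' Strength assortativity of a band layer
#'
#' Edge-weight-weighted Pearson correlation of the (weighted) degrees, i.e.
#' strengths, of the two endpoints across edges: the network's selective
#' connectivity mixing. Undefined (NA) when fewer than 2 positive-weight
#' edges exist or when the endpoint strengths have zero variance.
#'
#' @param layer 6 x 6 symmetric non-negative weight matrix.
#' @return Value in `[-1, 1]`, or `NA` when undefined.
#' @export
assortativity <- function(layer) {
  m <- layer_matrix(layer)
  s <- rowSums(m)
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  if (nrow(ut) < 2L) return(NA_real_)
  w <- m[cbind(ut[, 1], ut[, 2])]
  # each undirected edge contributes both orientations
  xs <- c(s[ut[, 1]], s[ut[, 2]])
  ys <- c(s[ut[, 2]], s[ut[, 1]])
  ww <- c(w, w)
  wm <- function(v) sum(ww * v) / sum(ww)
  cx <- xs - wm(xs); cy <- ys - wm(ys)
  vx <- sum(ww * cx^2); vy <- sum(ww * cy^2)
  if (vx <= 1e-12 * sum(ww) * max(xs^2, 1) || vy <= 1e-12 * sum(ww) * max(ys^2, 1)) {
    return(NA_real_)
  }
  sum(ww * cx * cy) / sqrt(vx * vy)
}

#' Global efficiency of a band layer
#'
#' Mean over node pairs of the inverse shortest path length, with edge
#' lengths `1 / weight` (the dominant convention for coherence-weighted
#' networks); absent (zero-weight) edges carry no path and disconnected
#' pairs contribute 0. Functional integration of the layer.
#'
#' @param layer 6 x 6 symmetric non-negative weight matrix.
#' @return Value >= 0.
#' @export
global_efficiency <- function(layer) {
  m <- layer_matrix(layer)
  if (all(m == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected", weighted = TRUE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Weighted clustering coefficients of a band layer
#'
#' Geometric-mean (Onnela-type) triangle formulation on weights normalized
#' by the layer maximum:
#' `c_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` with
#' `k_i` the number of positive-weight neighbours; nodes with `k_i < 2`
#' get 0. Functional segregation per muscle.
#'
#' @param layer 6 x 6 symmetric non-negative weight matrix.
#' @return Named vector of 6 values in `[0, 1]`.
#' @export
weighted_clustering <- function(layer) {
  m <- layer_matrix(layer)
  k <- rowSums(m > 0)
  mx <- max(m)
  if (mx == 0) return(setNames(rep(0, 6), MN_CHANNELS))
  a <- (m / mx)^(1 / 3)
  tri <- diag(a %*% a %*% a)
  out <- ifelse(k < 2, 0, tri / (k * pmax(k - 1, 1)))
  setNames(out, MN_CHANNELS)
}

# Right/left homologous edges for each muscle-pair type.
LATERAL_EDGES <- list(
  TEMP_MAS = list(right = c("RTEMP", "RMAS"), left = c("LTEMP", "LMAS")),
  TEMP_ABD = list(right = c("RTEMP", "RABD"), left = c("LTEMP", "LABD")),
  MAS_ABD  = list(right = c("RMAS", "RABD"), left = c("LMAS", "LABD"))
)

#' Laterality index of a band layer
#'
#' Difference between the weight of the specified right-side edge and its
#' left-side counterpart, normalized by the sum of all 15 edge weights of
#' the same band layer; 0 when the layer sum is 0. Positive values mean
#' right-dominant functional connectivity.
#'
#' @param layer 6 x 6 symmetric non-negative weight matrix.
#' @param pair_type One of `"TEMP_MAS"` (agonist pair), `"TEMP_ABD"`,
#'   `"MAS_ABD"` (antagonist pairs).
#' @return Value in `[-1, 1]`.
#' @export
laterality_index <- function(layer, pair_type = c("TEMP_MAS", "TEMP_ABD", "MAS_ABD")) {
  m <- layer_matrix(layer)
  dimnames(m) <- list(MN_CHANNELS, MN_CHANNELS)
  pair_type <- match.arg(pair_type)
  tot <- sum(m[upper.tri(m)])
  if (tot == 0) return(0)
  ed <- LATERAL_EDGES[[pair_type]]
  (m[ed$right[1], ed$right[2]] - m[ed$left[1], ed$left[2]]) / tot
}

#' Edgewise feature vector of a multiplex network
#'
#' The 36 edgewise features: per band, mean nodal strength, assortativity
#' and global efficiency (9), weighted clustering per muscle (18) and
#' laterality per muscle-pair type (9). Together with the 12 nodal
#' features this completes the 48-feature vector.
#'
#' @param net A `multiplex_network` from [multiplex_weights()].
#' @return A one-row tibble with 36 named columns.
#' @export
edgewise_features <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  out <- list()
  for (b in names(MN_BANDS)) {
    lay <- net$layers[[b]]
    if (anyNA(lay)) {
      warn(sprintf("band %s has missing edge weights; its features are NA.", b))
      out[[paste0("nodstr_", b)]] <- NA_real_
      out[[paste0("ac_", b)]] <- NA_real_
      out[[paste0("ge_", b)]] <- NA_real_
      for (ch in MN_CHANNELS) out[[paste0("wcc_", ch, "_", b)]] <- NA_real_
      for (pt in names(LATERAL_EDGES)) out[[paste0("lat_", pt, "_", b)]] <- NA_real_
      next
    }
    out[[paste0("nodstr_", b)]] <- mean_nodal_strength(lay)
    out[[paste0("ac_", b)]] <- assortativity(lay)
    out[[paste0("ge_", b)]] <- global_efficiency(lay)
    wcc <- weighted_clustering(lay)
    for (ch in MN_CHANNELS) out[[paste0("wcc_", ch, "_", b)]] <- unname(wcc[ch])
    for (pt in names(LATERAL_EDGES)) {
      out[[paste0("lat_", pt, "_", b)]] <- laterality_index(lay, pt)
    }
  }
  nm <- mn_feature_names()
  nm <- nm[!grepl("^(density|specradRatio)_", nm)]
  tibble::as_tibble_row(out[nm])
}
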