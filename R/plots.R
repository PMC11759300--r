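# ggplot2 visualizations of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Hexagonal node layout used for all network drawings: right column RTEMP
# / RMAS / RABD, left column LTEMP / LMAS / LABD.
node_layout <- function() {
  tibble::tibble(
    node = MN_CHANNELS,
    x = rep(c(1, -1), 3L),
    y = rep(c(1, 0, -1), each = 2L)
  )
}

#' Plot a multiplex coherence network
#'
#' One panel per frequency band; edge width encodes the Fisher-z
#' coherence weight, zero-weight edges are omitted.
#'
#' @param net A `multiplex_network`.
#' @return A ggplot object.
#' @export
plot_network <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  lay <- node_layout()
  edges <- tidyr::separate(net$edge_table, "edge", c("from", "to"), sep = "-")
  edges <- dplyr::left_join(edges, dplyr::rename(lay, from_x = "x", from_y = "y"),
                            by = c(from = "node"))
  edges <- dplyr::left_join(edges, dplyr::rename(lay, to_x = "x", to_y = "y"),
                            by = c(to = "node"))
  edges$band <- factor(edges$band, levels = names(MN_BANDS))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::filter(edges, .data$weight > 0),
      ggplot2::aes(x = .data$from_x, y = .data$from_y,
                   xend = .data$to_x, yend = .data$to_y,
                   linewidth = .data$weight),
      colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_point(data = lay, ggplot2::aes(.data$x, .data$y), size = 9,
                        colour = "grey25") +
    ggplot2::geom_text(data = lay, ggplot2::aes(.data$x, .data$y, label = .data$node),
                       colour = "white", size = 2.4) +
    ggplot2::facet_wrap(~band) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.6, 1.6), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "Fisher z")
}

#' @export
autoplot.multiplex_network <- function(object, ...) plot_network(object)

#' Loading heatmap of a factor model
#'
#' @param object A `muscle_factor_model`.
#' @param threshold Loadings below this absolute value are blanked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.muscle_factor_model <- function(object, threshold = 0, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = rev(object$feature_names))
  df$loading[abs(df$loading) < threshold] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$feature,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", na.value = "grey95") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading")
}

#' ROC curve of a classifier report
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s: AUC %.2f", toupper(object$algorithm),
                      object$metrics$auc)
    )
}

#' Group-wise boxplots of selected features
#'
#' @param features Feature table with a `stage` (or `group`) column.
#' @param which Feature column names to plot (default: the per-band mean
#'   nodal strength).
#' @return A ggplot object.
#' @export
plot_feature_profiles <- function(features,
                                  which = paste0("nodstr_", names(MN_BANDS))) {
  grp <- if ("stage" %in% colnames(features)) "stage" else "group"
  df <- tidyr::pivot_longer(features[c(grp, which)], dplyr::all_of(which),
                            names_to = "feature", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data[[grp]], .data$value,
                                   fill = .data[[grp]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}
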