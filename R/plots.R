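# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_step geom_line geom_point geom_col
#'   geom_segment geom_vline labs theme_minimal scale_x_continuous
NULL

#' Plot the edge-length distribution ratio used for threshold estimation
#'
#' Shows `p_all / p_intra - 1` per log10 length bin; the truncation
#' threshold sits where this departs from zero and keeps increasing.
#'
#' @param hist An [edge_length_histogram()] result.
#' @param d_t Optional threshold to mark.
#' @return A ggplot object.
#' @export
plot_edge_histogram <- function(hist, d_t = NULL) {
  df <- hist |>
    mutate(mid = (.data$bin_lo + .data$bin_hi) / 2,
           ratio_minus_1 = ifelse(.data$p_intra > 0,
                                  .data$p_all / .data$p_intra - 1, NA_real_))
  p <- ggplot(df, aes(x = .data$mid, y = .data$ratio_minus_1)) +
    geom_line(na.rm = TRUE) + geom_point(na.rm = TRUE) +
    labs(x = "log10 edge length", y = "P_all / P_intra - 1") +
    theme_minimal()
  if (!is.null(d_t)) p <- p + geom_vline(xintercept = log10(d_t), linetype = 2)
  p
}

#' @rdname run_msc
#' @param object Object to plot.
#' @method autoplot msc_hierarchy
#' @export
autoplot.msc_hierarchy <- function(object, ...) {
  sizes <- object$assignments |>
    filter(!.data$is_outlier) |>
    dplyr::count(.data$level, .data$cluster_label, name = "size") |>
    dplyr::count(.data$level, .data$size, name = "n_clusters")
  ggplot(sizes, aes(x = .data$size, y = .data$n_clusters)) +
    geom_col() +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    labs(x = "cluster size (sequences)", y = "number of clusters") +
    theme_minimal()
}

#' @rdname spanning_forest
#' @param object An `msc_forest`.
#' @param seed Layout seed (the force-directed layout is stochastic).
#' @param ... Unused.
#' @method autoplot msc_forest
#' @export
autoplot.msc_forest <- function(object, seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = object$nodes$node)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$node)
  edges <- object$edges |>
    mutate(x = nodes$x[pos[.data$from]], y = nodes$y[pos[.data$from]],
           xend = nodes$x[pos[.data$to]], yend = nodes$y[pos[.data$to]])
  p <- ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey60")
  if ("ref_label" %in% names(nodes)) {
    p <- p + geom_point(data = nodes,
                        aes(x = .data$x, y = .data$y, colour = .data$ref_label))
  } else {
    p <- p + geom_point(data = nodes, aes(x = .data$x, y = .data$y))
  }
  p + labs(x = NULL, y = NULL) + theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname selection_summary
#' @param object A `selection_summary`.
#' @method autoplot selection_summary
#' @export
autoplot.selection_summary <- function(object, ...) {
  ggplot(object$cdf, aes(x = .data$dnds, y = .data$cumulative)) +
    geom_step() +
    geom_vline(xintercept = 1, linetype = 2) +
    labs(x = "dN/dS", y = "cumulative fraction of pairs") +
    theme_minimal()
}

#' @rdname tune_threshold
#' @param object A `detection_model`.
#' @method autoplot detection_model
#' @export
autoplot.detection_model <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$v_t, y = .data$f)) +
    geom_line() +
    geom_vline(xintercept = object$v_t, linetype = 2) +
    labs(x = "threshold V_t (log10 distance)", y = "F measure") +
    theme_minimal()
}
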