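# ggplot2 views of the main result types.

#' Plot a similarity matrix as a heatmap
#'
#' @param object A `cyto_similarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_similarity <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("region_j", "region_i")
  ggplot2::ggplot(bind_rows(df, df2),
                  ggplot2::aes(x = factor(.data$region_i),
                               y = factor(.data$region_j),
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "region", y = "region",
                  fill = paste0("similarity\n(", object$transform, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a group network's edge prevalence and consensus edges
#'
#' @param object A `cyto_group_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_group_network <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prevalence,
                                   fill = .data$connected)) +
    ggplot2::geom_histogram(bins = object$n_subjects + 1, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "subject prevalence", y = "region pairs",
                  fill = "consensus edge") +
    ggplot2::theme_minimal()
}

#' Edge-level association plots from a pipeline report
#'
#' Scatter of profile similarity against (gaussianized) connection weight
#' over consensus edges, the core edge-level association of the analysis.
#'
#' @param object A `cyto_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_report <- function(object, ...) {
  conn <- object$edges[object$edges$connected, ]
  ggplot2::ggplot(conn, ggplot2::aes(x = .data$sim, y = .data$nos_g)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "profile similarity (gaussianized)",
                  y = "connection weight (gaussianized NOS)") +
    ggplot2::theme_minimal()
}

#' Violin plot of similarity for connected versus nonconnected pairs
#'
#' @param report A `cyto_report`.
#' @return A ggplot object.
#' @export
plot_edge_groups <- function(report) {
  ggplot2::ggplot(report$edges,
                  ggplot2::aes(x = .data$connected, y = .data$sim)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = "connected", y = "profile similarity (gaussianized)") +
    ggplot2::theme_minimal()
}

#' Node-level scatter of regional similarity against a graph metric
#'
#' @param report A `cyto_report`.
#' @param metric Column of the nodal table to plot against
#'   (default `"strength_nos"`).
#' @return A ggplot object.
#' @export
plot_nodal_scatter <- function(report, metric = "strength_nos") {
  ggplot2::ggplot(report$nodal,
                  ggplot2::aes(x = .data[[metric]],
                               y = .data$mean_similarity)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = metric, y = "regional mean similarity") +
    ggplot2::theme_minimal()
}
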