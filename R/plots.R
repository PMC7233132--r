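#' Plot neighborhoods colored by region
#'
#' Positional plot of neighborhood centers, color-coded by region
#' assignment — the standard tissue-region map.
#'
#' @param nbhd A neighborhood tibble.
#' @param assignment Region assignment tibble (`nbhd_id`, `region`,
#'   optional `annotated_region`); omit to color by total cell count.
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_regions <- function(nbhd, assignment = NULL, point_size = 0.8) {
  df <- tibble::as_tibble(nbhd)
  if (!is.null(assignment)) {
    col <- if ("annotated_region" %in% names(assignment)) "annotated_region"
           else "region"
    df$region <- factor(assignment[[col]][match(df$nbhd_id,
                                                assignment$nbhd_id)])
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     color = .data$region)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (µm)", y = "y (µm)", color = "region") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     color = .data$n_total)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (µm)", y = "y (µm)",
                    color = "cells") +
      ggplot2::theme_minimal()
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.pseudo_space <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -c("pseudo_rank", "nbhd_id", "sort_key"),
                              names_to = "phenotype", values_to = "curve")
  ggplot2::ggplot(long, ggplot2::aes(.data$pseudo_rank, .data$curve,
                                     color = .data$phenotype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudo-space (neighborhood rank)",
                  y = "normalized abundance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.region_model <- function(object, ...) {
  ggplot2::ggplot(object$db_curve, ggplot2::aes(.data$k, .data$db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "candidate region count",
                  y = "Davies-Bouldin index") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.spatial_cor <- function(object, ...) {
  long <- long_cor(object$cohort_r, NULL)
  ggplot2::ggplot(long, ggplot2::aes(.data$phenotype_a, .data$phenotype_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tissue_embedding <- function(object, color = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(color)) df$color <- factor(color)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = paste0(attr(object, "method"), " 1"),
                  y = paste0(attr(object, "method"), " 2"))
  if (is.null(color)) p + ggplot2::geom_point(size = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$color), size = 0.6) +
    ggplot2::labs(color = "region")
}

#' @exportS3Method ggplot2::autoplot
autoplot.region_graph <- function(object, ...) {
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes
  nodes$px <- lay[, 1]
  nodes$py <- lay[, 2]
  ed <- object$edges
  ed$x <- nodes$px[match(ed$from, nodes$region)]
  ed$y <- nodes$py[match(ed$from, nodes$region)]
  ed$xend <- nodes$px[match(ed$to, nodes$region)]
  ed$yend <- nodes$py[match(ed$to, nodes$region)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          color = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$px, .data$py,
                                     size = .data$n_nbhd,
                                     color = .data$region)) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "neighborhoods", linewidth = "contact %")
}
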