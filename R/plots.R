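#' Plot a differential connectivity profile
#'
#' Per-metabolite connectivity difference with significant metabolites
#' (FDR-adjusted p below the stored threshold) highlighted.
#'
#' @param object A [differential_connectivity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabnet_diffcon
#' @export
autoplot.metabnet_diffcon <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$index <- seq_len(nrow(df))
  pair <- attr(object, "pair") %||% c("a", "b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$delta,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red3")) +
    ggplot2::labs(
      x = "Metabolite", y = "Connectivity difference",
      colour = "FDR significant",
      title = paste("Differential connectivity:", paste(pair, collapse = " vs "))
    ) +
    ggplot2::theme_minimal()
}

#' Biplot of a network-topology PCA
#'
#' @param object A [topology_pca()] result.
#' @param loading_scale Multiplier applied to the loading arrows so they
#'   are visible on the score scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topology_pca
#' @export
autoplot.topology_pca <- function(object, loading_scale = NULL, ...) {
  sc <- object$scores
  ld <- object$loadings
  loading_scale <- loading_scale %||%
    (0.8 * max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(ld$PC1, ld$PC2))))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$network), alpha = 0.7) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * loading_scale,
                   yend = .data$PC2 * loading_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * loading_scale * 1.08,
                   y = .data$PC2 * loading_scale * 1.08,
                   label = .data$metric),
      size = 2.8, colour = "grey30"
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2]),
      title = "Topology PCA"
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of pathway enrichment results
#'
#' @param object A [hypergeometric_enrich()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabnet_enrichment
#' @export
autoplot.metabnet_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pathway_name <- stats::reorder(df$pathway_name, -log10(df$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$pathway_name)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k_matched,
                                     colour = .data$impact)) +
    ggplot2::scale_colour_gradient(low = "gold", high = "red3") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  size = "Matched", colour = "Impact") +
    ggplot2::theme_minimal()
}

#' Plot an association network
#'
#' Simple force-directed layout with edge colour by correlation sign and
#' node size by connectivity.
#'
#' @param net An `assoc_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 42L) {
  stopifnot(inherits(net, "assoc_network"))
  g <- as_igraph(net)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(net$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(
    dplyr::left_join(net$edges,
                     dplyr::select(nodes, from = "name", x0 = "x", y0 = "y"),
                     by = "from"),
    dplyr::select(nodes, to = "name", x1 = "x", y1 = "y"),
    by = "to"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data$weight > 0, alpha = .data$probability)
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "navy"),
                                 labels = c(`TRUE` = "positive", `FALSE` = "negative")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$connectivity),
                        colour = "grey25") +
    ggplot2::labs(colour = "Correlation sign", alpha = "Edge probability",
                  size = "Connectivity") +
    ggplot2::theme_void()
}
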