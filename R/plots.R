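#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout with node size proportional to haplotype
#' multiplicity; median vectors are drawn as small filled points, edges
#' are labelled with their mutation counts.
#'
#' @param object A [median_joining()] network.
#' @param seed Layout seed.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[, 1L], y = xy[, 2L],
           kind = ifelse(.data$is_median, "median vector", "observed"))
  pos <- setNames(seq_len(nrow(nodes)), nodes$node)
  edges <- object$edges |>
    mutate(x = xy[pos[.data$from], 1L], y = xy[pos[.data$from], 2L],
           xend = xy[pos[.data$to], 1L], yend = xy[pos[.data$to], 2L])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_label(
      data = edges,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$mutations),
      size = 2.5, label.size = 0) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind,
                   size = pmax(.data$multiplicity, 0.5))) +
    ggplot2::geom_text(
      data = nodes[!nodes$is_median, ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 8, guide = "none") +
    ggplot2::scale_colour_manual(
      values = c("median vector" = "firebrick", "observed" = "steelblue"),
      name = NULL) +
    ggplot2::theme_void()
}

#' Plot a UPGMA tree as a dendrogram
#'
#' @param object An `upgma_tree` (optionally with bootstrap node labels).
#' @param ... Unused.
#' @returns A ggplot object (segments plus tip and support labels).
#' @method autoplot upgma_tree
#' @export
autoplot.upgma_tree <- function(object, ...) {
  n_tip <- ape::Ntip(object)
  depth <- node_depths(object)
  height <- max(depth) - depth  # node height above the tips
  # tip y-positions in plotted order
  ord <- reorder(object, "cladewise")
  tip_order <- ord$edge[ord$edge[, 2L] <= n_tip, 2L]
  y <- numeric(n_tip + object$Nnode)
  y[tip_order] <- seq_len(n_tip)
  # internal nodes: mean of children, computed bottom-up
  for (node in rev(sort(unique(object$edge[, 1L])))) {
    kids <- object$edge[object$edge[, 1L] == node, 2L]
    y[node] <- mean(y[kids])
  }
  seg <- purrr::map_dfr(seq_len(nrow(object$edge)), function(e) {
    p <- object$edge[e, 1L]; c_ <- object$edge[e, 2L]
    tibble(x = height[p], xend = height[c_], y = y[c_], yend = y[c_],
           vx = height[p], vy = y[p], vyend = y[c_])
  })
  labs <- tibble(x = height[seq_len(n_tip)], y = y[seq_len(n_tip)],
                 label = object$tip.label)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$vx, xend = .data$vx,
                                       y = .data$vy, yend = .data$vyend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_reverse(expand = ggplot2::expansion(mult = c(0.05, 0.25))) +
    ggplot2::labs(x = "distance", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (!is.null(object$node.label)) {
    sup <- tibble(x = height[n_tip + seq_len(object$Nnode)],
                  y = y[n_tip + seq_len(object$Nnode)],
                  label = object$node.label)
    p <- p + ggplot2::geom_text(data = sup,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$label),
                                vjust = -0.6, size = 2.8,
                                colour = "grey30")
  }
  p
}

#' Plot a group-comparison similarity matrix
#'
#' Heat-map of the pairwise similarity indices from [comparison_table()].
#'
#' @param object A [comparison_table()] tibble.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
plot_similarity_matrix <- function(object, ...) {
  both <- bind_rows(
    object,
    object |> dplyr::rename(group_a = "group_b", group_b = "group_a"))
  ggplot2::ggplot(both,
                  ggplot2::aes(x = .data$group_a, y = .data$group_b,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data$similarity_2dp)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#fee8c8", high = "#41ae76",
                                 limits = c(0, 1), name = "similarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
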