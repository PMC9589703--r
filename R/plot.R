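# ggplot2 displays for networks, profiles and diffusion traces.

#' Plot a social network
#'
#' Force-directed layout with vertices coloured by their community label
#' combination (overlapping memberships show as their own combination, e.g.
#' `"blue+red"`); directed networks draw arrows.
#'
#' @param object A `social_network`.
#' @param layout_seed Seed for the force-directed layout, for reproducible
#'   figures.
#' @param label_vertices Draw vertex names?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot social_network
#' @export
autoplot.social_network <- function(object, layout_seed = 1,
                                    label_vertices = TRUE, ...) {
  ig <- as_igraph(object)
  xy <- with_local_seed(layout_seed, igraph::layout_with_fr(ig))
  nodes <- tibble::tibble(
    vertex = object$graph$vertices,
    x = xy[, 1], y = xy[, 2],
    communities = vapply(object$membership, function(m) {
      if (length(m) == 0) "(none)" else paste(m, collapse = "+")
    }, character(1))
  )
  em <- object$graph$edges
  edges <- tibble::tibble(
    x = nodes$x[match(em[, 1], nodes$vertex)],
    y = nodes$y[match(em[, 1], nodes$vertex)],
    xend = nodes$x[match(em[, 2], nodes$vertex)],
    yend = nodes$y[match(em[, 2], nodes$vertex)]
  )
  arrow <- if (object$graph$directed) {
    ggplot2::arrow(length = ggplot2::unit(2.5, "mm"), type = "closed")
  } else NULL
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50", arrow = arrow
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$communities),
      size = 4
    ) +
    ggplot2::labs(colour = "communities") +
    ggplot2::theme_void()
  if (label_vertices) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$vertex),
      vjust = -1.2, size = 3
    )
  }
  p
}

#' Plot a component profile
#'
#' Bar chart of component sizes in canonical (non-increasing) order.
#'
#' @param object A `component_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot component_profile
#' @export
autoplot.component_profile <- function(object, ...) {
  d <- tibble::tibble(component = factor(seq_along(object)),
                      size = as.integer(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "component (largest first)", y = "vertices") +
    ggplot2::theme_minimal()
}

#' Plot a diffusion trace
#'
#' Number of new adopters per synchronous influence round.
#'
#' @param object A `diffusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffusion_result
#' @export
autoplot.diffusion_result <- function(object, ...) {
  d <- tibble::tibble(
    round = seq_len(max(object$rounds, 1)),
    adopters = if (object$rounds == 0) 0L else
      lengths(object$adopters_per_round)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$round, y = .data$adopters)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_x_continuous(breaks = d$round) +
    ggplot2::labs(x = "influence round", y = "new adopters") +
    ggplot2::theme_minimal()
}
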