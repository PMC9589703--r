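# Bare graphs: the codomain of the binary relations between communities.
# Internal representation is deliberately lean (sorted character vector of
# vertices + canonical two-column character matrix of edges) so that the
# calculus stays fast on the thousands of small graphs the planners and the
# property suites churn through; tibble views are provided for analysis.

#' Construct a graph
#'
#' Creates a simple graph over opaque string vertex identifiers. Undirected
#' edges are stored in one canonical orientation (lexicographically smaller
#' endpoint first) and duplicate edges collapse to one, so two graphs with the
#' same vertex and edge sets are `identical()`. Self-loops are rejected.
#'
#' @param vertices Character vector of vertex identifiers. Endpoints appearing
#'   in `edges` are added automatically.
#' @param edges Edges as a two-column matrix or data frame (`from`, `to`), a
#'   list of length-2 vectors, or `NULL` for no edges.
#' @param directed Logical; directed edges? Undirected is the default, as for
#'   friendship or co-membership ties; directed graphs model e.g. assimilative
#'   influence.
#' @return An object of class `ct_graph`.
#' @examples
#' g <- graph(edges = list(c("a", "b"), c("b", "c")))
#' graph_order(g)
#' @export
graph <- function(vertices = character(), edges = NULL, directed = FALSE) {
  em <- as_edge_matrix(edges)
  if (nrow(em) > 0 && any(em[, 1] == em[, 2])) {
    stop("self-loops are not allowed: ",
         paste(unique(em[em[, 1] == em[, 2], 1]), collapse = ", "),
         call. = FALSE)
  }
  em <- canonical_edges(em, directed)
  dup <- duplicated(edge_keys(em))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed", call. = FALSE)
    em <- em[!dup, , drop = FALSE]
  }
  vs <- sort(unique(c(as.character(vertices), as.vector(em))))
  new_graph(vs, em, isTRUE(directed))
}

# low-level constructor: assumes vertices sorted/unique, edges canonical
new_graph <- function(vertices, edges, directed) {
  structure(
    list(vertices = vertices, edges = edges, directed = directed),
    class = "ct_graph"
  )
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.atomic(edges) && length(edges) == 0)) {
    return(matrix(character(), ncol = 2))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    if (!all(lengths(edges) == 2)) {
      stop("each edge must have exactly two endpoints", call. = FALSE)
    }
    return(matrix(as.character(unlist(edges)), ncol = 2, byrow = TRUE))
  }
  if (is.data.frame(edges)) {
    stopifnot(ncol(edges) >= 2)
    return(cbind(as.character(edges[[1]]), as.character(edges[[2]])))
  }
  if (is.matrix(edges)) {
    stopifnot(ncol(edges) == 2)
    storage.mode(edges) <- "character"
    dimnames(edges) <- NULL
    return(edges)
  }
  if (is.atomic(edges) && length(edges) == 2) {
    return(matrix(as.character(edges), ncol = 2))
  }
  stop("cannot interpret `edges`", call. = FALSE)
}

# orient undirected edges low-high, then sort rows; no deduplication here
canonical_edges <- function(em, directed) {
  if (nrow(em) == 0) return(matrix(character(), ncol = 2))
  if (!directed) {
    flip <- em[, 1] > em[, 2]
    if (any(flip)) em[flip, ] <- em[flip, 2:1]
  }
  em[order(em[, 1], em[, 2]), , drop = FALSE]
}

edge_keys <- function(em) {
  if (nrow(em) == 0) return(character())
  paste(em[, 1], em[, 2], sep = "\r")
}

#' @export
print.ct_graph <- function(x, ...) {
  cat(sprintf("<ct_graph: %d vertices, %d %s edges>\n",
              length(x$vertices), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  if (length(x$vertices)) {
    cat("vertices:", paste(utils::head(x$vertices, 20), collapse = ", "),
        if (length(x$vertices) > 20) "..." else "", "\n")
  }
  if (nrow(x$edges)) {
    sep <- if (x$directed) " -> " else " -- "
    shown <- utils::head(seq_len(nrow(x$edges)), 20)
    cat("edges:", paste(x$edges[shown, 1], x$edges[shown, 2], sep = sep,
                        collapse = ", "),
        if (nrow(x$edges) > 20) "..." else "", "\n")
  }
  invisible(x)
}

#' Graph accessors
#'
#' @param g A `ct_graph`.
#' @return `graph_vertices()`: character vector of vertex names;
#'   `graph_edges()`: a tibble with columns `from` and `to`;
#'   `graph_order()` / `graph_size()`: vertex / edge counts;
#'   `is_directed_graph()`: logical.
#' @export
graph_vertices <- function(g) {
  stopifnot(inherits(g, "ct_graph"))
  g$vertices
}

#' @rdname graph_vertices
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "ct_graph"))
  tibble::tibble(from = g$edges[, 1], to = g$edges[, 2])
}

#' @rdname graph_vertices
#' @export
graph_order <- function(g) length(graph_vertices(g))

#' @rdname graph_vertices
#' @export
graph_size <- function(g) nrow(g$edges)

#' @rdname graph_vertices
#' @export
is_directed_graph <- function(g) {
  stopifnot(inherits(g, "ct_graph"))
  g$directed
}

#' @method as_tibble ct_graph
#' @export
as_tibble.ct_graph <- function(x, ...) graph_edges(x)

#' Test two graphs for equality
#'
#' Vertex sets, edge sets and directedness must all agree; edge order and
#' orientation of undirected edges are immaterial because both graphs are in
#' canonical form.
#'
#' @param g,g2 `ct_graph` objects.
#' @return Logical scalar.
#' @export
graph_identical <- function(g, g2) {
  stopifnot(inherits(g, "ct_graph"), inherits(g2, "ct_graph"))
  identical(g$directed, g2$directed) &&
    identical(g$vertices, g2$vertices) &&
    identical(unname(g$edges), unname(g2$edges))
}

check_same_directedness <- function(g, g2) {
  if (!identical(g$directed, g2$directed)) {
    stop("cannot combine a directed with an undirected graph", call. = FALSE)
  }
}

#' Binary relations between graphs: intersection, union, subtraction
#'
#' The three graph-valued binary relations underpinning the topological
#' relationship calculus. `graph_intersect()` intersects vertex and edge sets;
#' `graph_union()` unions them; `graph_subtract()` removes the second graph's
#' vertices and edges from the first, where removing a vertex also removes
#' every edge incident to it.
#'
#' @param g,g2 `ct_graph` objects with the same directedness.
#' @return A `ct_graph`.
#' @examples
#' b <- graph(edges = list(c("a","b"), c("a","c"), c("b","c")))
#' r <- graph(edges = list(c("c","d"), c("d","e")))
#' graph_intersect(b, r)  # single shared vertex c, no shared edges
#' graph_subtract(b, r)   # a, b and the edge between them survive
#' @export
graph_intersect <- function(g, g2) {
  check_same_directedness(g, g2)
  vs <- intersect(g$vertices, g2$vertices)
  keep <- edge_keys(g$edges) %in% edge_keys(g2$edges)
  new_graph(vs, g$edges[keep, , drop = FALSE], g$directed)
}

#' @rdname graph_intersect
#' @export
graph_union <- function(g, g2) {
  check_same_directedness(g, g2)
  vs <- sort(unique(c(g$vertices, g2$vertices)))
  em <- rbind(g$edges, g2$edges)
  em <- em[!duplicated(edge_keys(em)), , drop = FALSE]
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  new_graph(vs, em, g$directed)
}

#' @rdname graph_intersect
#' @export
graph_subtract <- function(g, g2) {
  check_same_directedness(g, g2)
  vs <- setdiff(g$vertices, g2$vertices)
  keep <- !(edge_keys(g$edges) %in% edge_keys(g2$edges))
  em <- g$edges[keep, , drop = FALSE]
  surv <- em[, 1] %in% vs & em[, 2] %in% vs
  new_graph(vs, em[surv, , drop = FALSE], g$directed)
}

#' Component profile of a graph
#'
#' Maps a graph to the multiset of its connected-component vertex counts, the
#' topological descriptor on which all relationship conditions are phrased.
#' Directed graphs are profiled under weak connectivity, treating each
#' directed tie as a connection.
#'
#' @param g A `ct_graph`.
#' @return A `component_profile`: an integer vector of component sizes in
#'   non-increasing order (the canonical form of the multiset). The sizes sum
#'   to the number of vertices in `g`.
#' @examples
#' component_profile(graph(vertices = c("a","b","e","d"),
#'                         edges = list(c("a","b"))))  # {2, 1, 1}
#' @export
component_profile <- function(g) {
  stopifnot(inherits(g, "ct_graph"))
  n <- length(g$vertices)
  if (n == 0) return(new_component_profile(integer()))
  if (nrow(g$edges) == 0) return(new_component_profile(rep(1L, n)))
  idx <- match(g$edges, g$vertices)  # column-major: from then to
  ig <- igraph::make_graph(as.vector(t(matrix(idx, ncol = 2))),
                           n = n, directed = g$directed)
  sizes <- igraph::components(ig, mode = "weak")$csize
  new_component_profile(as.integer(sizes))
}

new_component_profile <- function(sizes) {
  structure(sort(as.integer(sizes), decreasing = TRUE),
            class = "component_profile")
}

#' Construct a component profile directly
#'
#' @param sizes Positive integer component sizes, any order.
#' @return A `component_profile` in canonical non-increasing order.
#' @export
as_component_profile <- function(sizes) {
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 1)) {
    stop("component sizes must be positive integers", call. = FALSE)
  }
  new_component_profile(sizes)
}

#' @export
print.component_profile <- function(x, ...) {
  cat("{", paste(unclass(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
format.component_profile <- function(x, ...) {
  paste0("{", paste(unclass(x), collapse = ", "), "}")
}

#' Multiset equality of component profiles
#'
#' @param x,y `component_profile` objects or bare integer vectors.
#' @return Logical scalar: do the two multisets coincide?
#' @export
profile_equal <- function(x, y) {
  identical(sort(as.integer(x), decreasing = TRUE),
            sort(as.integer(y), decreasing = TRUE))
}

#' Convert a graph or social network to an igraph object
#'
#' Vertex names are preserved; for a social network a `communities` vertex
#' attribute carries each vertex's semicolon-separated community labels.
#'
#' @param x A `ct_graph` or `social_network`.
#' @param ... Unused.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.ct_graph <- function(x, ...) {
  ig <- igraph::make_empty_graph(n = length(x$vertices), directed = x$directed)
  ig <- igraph::set_vertex_attr(ig, "name", value = x$vertices)
  if (nrow(x$edges) > 0) {
    idx <- match(x$edges, x$vertices)
    ig <- igraph::add_edges(ig, as.vector(t(matrix(idx, ncol = 2))))
  }
  ig
}
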