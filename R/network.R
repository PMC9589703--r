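# Social networks: a graph plus typed, possibly overlapping, crisp community
# memberships. Communities are realised as vertex-induced subgraphs derived on
# demand, never stored, so no edit can leave a community's edge set out of
# sync with the graph.

#' Construct a social network
#'
#' A social network is a simple graph together with a set of community type
#' labels and a crisp membership map assigning each vertex a (possibly empty)
#' subset of those labels. A vertex may belong to zero, one, or several
#' communities. Vertices mentioned only in `membership` are added to the graph
#' as isolated vertices.
#'
#' @param graph A `ct_graph`, or anything `graph()` accepts as `edges`.
#' @param membership Named list mapping vertex name to a character vector of
#'   community labels, or a data frame with columns `vertex` and `labels`
#'   (semicolon-separated string, empty for no community). Vertices absent
#'   from `membership` belong to no community.
#' @param labels Character vector of community type names. Defaults to the
#'   sorted union of labels used in `membership`.
#' @param directed Used only when `graph` is not already a `ct_graph`.
#' @return An object of class `social_network`.
#' @examples
#' net <- social_network(
#'   graph(edges = list(c("a","b"), c("a","c"), c("b","c"),
#'                      c("c","d"), c("d","e"))),
#'   membership = list(a = "blue", b = "blue", c = c("blue", "red"),
#'                     d = "red", e = "red")
#' )
#' community_subgraph(net, "blue")
#' @export
social_network <- function(graph, membership = list(), labels = NULL,
                           directed = FALSE) {
  if (!inherits(graph, "ct_graph")) {
    graph <- graph(edges = graph, directed = directed)
  }
  membership <- as_membership_list(membership)
  extra <- setdiff(names(membership), graph$vertices)
  if (length(extra) > 0) {
    graph <- new_graph(sort(c(graph$vertices, extra)), graph$edges,
                       graph$directed)
  }
  used <- sort(unique(unlist(membership, use.names = FALSE)))
  if (is.null(labels)) {
    labels <- used
  } else {
    labels <- sort(unique(as.character(labels)))
    bad <- setdiff(used, labels)
    if (length(bad) > 0) {
      stop("membership uses undeclared label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # complete, canonical membership: one sorted entry per vertex
  full <- stats::setNames(
    lapply(graph$vertices, function(v) {
      m <- membership[[v]]
      if (is.null(m)) character() else sort(unique(as.character(m)))
    }),
    graph$vertices
  )
  structure(list(graph = graph, labels = labels, membership = full),
            class = "social_network")
}

as_membership_list <- function(membership) {
  if (is.data.frame(membership)) {
    stopifnot(all(c("vertex", "labels") %in% names(membership)))
    return(stats::setNames(
      lapply(membership$labels, parse_label_field),
      as.character(membership$vertex)
    ))
  }
  if (is.null(membership)) return(list())
  stopifnot(is.list(membership))
  if (length(membership) > 0 && is.null(names(membership))) {
    stop("`membership` list must be named by vertex", call. = FALSE)
  }
  membership
}

parse_label_field <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network: %d vertices, %d %s edges, %d communities>\n",
              length(x$graph$vertices), nrow(x$graph$edges),
              if (x$graph$directed) "directed" else "undirected",
              length(x$labels)))
  for (l in x$labels) {
    m <- community_members(x, l)
    cat(sprintf("  %s: {%s}\n", l, paste(m, collapse = ", ")))
  }
  invisible(x)
}

#' Social network accessors
#'
#' @param net A `social_network`.
#' @param label A community label in `community_labels(net)`.
#' @return `network_graph()`: the underlying `ct_graph`;
#'   `community_labels()`: character vector of community types;
#'   `network_membership()`: named list vertex -> label subset;
#'   `community_members()`: sorted character vector of member vertices.
#' @export
network_graph <- function(net) {
  stopifnot(inherits(net, "social_network"))
  net$graph
}

#' @rdname network_graph
#' @export
community_labels <- function(net) {
  stopifnot(inherits(net, "social_network"))
  net$labels
}

#' @rdname network_graph
#' @export
network_membership <- function(net) {
  stopifnot(inherits(net, "social_network"))
  net$membership
}

check_label <- function(net, label) {
  if (!is.character(label) || length(label) != 1 || !(label %in% net$labels)) {
    stop("unknown community label: ", paste(label, collapse = ", "),
         call. = FALSE)
  }
}

#' @rdname network_graph
#' @export
community_members <- function(net, label) {
  stopifnot(inherits(net, "social_network"))
  check_label(net, label)
  vs <- names(net$membership)[
    vapply(net$membership, function(m) label %in% m, logical(1))
  ]
  sort(vs)
}

#' Vertex-induced subgraph of a community
#'
#' Realises the community map: the subgraph induced by the vertices carrying
#' `label`, with exactly those edges of the network whose endpoints both carry
#' it.
#'
#' @inheritParams network_graph
#' @return A `ct_graph`.
#' @export
community_subgraph <- function(net, label) {
  stopifnot(inherits(net, "social_network"))
  check_label(net, label)
  members <- community_members(net, label)
  em <- net$graph$edges
  keep <- em[, 1] %in% members & em[, 2] %in% members
  new_graph(members, em[keep, , drop = FALSE], net$graph$directed)
}

#' Ego community of a vertex
#'
#' The ego map sends a vertex to the graph containing the vertex and all of
#' its neighbours (out-neighbours when the network is directed) with an empty
#' edge set. The empty edge set is part of the definition: intersecting an ego
#' community with a community subgraph therefore yields only singleton
#' components, so the profile cardinality counts shared vertices.
#'
#' @inheritParams network_graph
#' @param v A vertex name.
#' @return A `ct_graph` with no edges.
#' @export
ego_community <- function(net, v) {
  stopifnot(inherits(net, "social_network"))
  if (!is.character(v) || length(v) != 1 || !(v %in% net$graph$vertices)) {
    stop("unknown vertex: ", paste(v, collapse = ", "), call. = FALSE)
  }
  em <- net$graph$edges
  if (net$graph$directed) {
    nb <- em[em[, 1] == v, 2]
  } else {
    nb <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
  }
  new_graph(sort(unique(c(v, nb))), matrix(character(), ncol = 2),
            net$graph$directed)
}

#' Test two social networks for equality
#'
#' Graph, label set and every vertex's membership must coincide.
#'
#' @param a,b `social_network` objects.
#' @return Logical scalar.
#' @export
network_identical <- function(a, b) {
  stopifnot(inherits(a, "social_network"), inherits(b, "social_network"))
  graph_identical(a$graph, b$graph) &&
    identical(a$labels, b$labels) &&
    identical(a$membership, b$membership)
}

#' @method as_tibble social_network
#' @export
as_tibble.social_network <- function(x, ...) {
  tibble::tibble(
    vertex = names(x$membership),
    communities = unname(x$membership)
  )
}

#' Tidy membership table of a social network
#'
#' One row per (vertex, community) pair; vertices in no community appear with
#' `community = NA`.
#'
#' @param x A `social_network`.
#' @param ... Unused.
#' @return A tibble with columns `vertex` and `community`.
#' @method tidy social_network
#' @export
tidy.social_network <- function(x, ...) {
  rows <- purrr::map2(
    names(x$membership), x$membership,
    function(v, m) {
      if (length(m) == 0) {
        tibble::tibble(vertex = v, community = NA_character_)
      } else {
        tibble::tibble(vertex = v, community = m)
      }
    }
  )
  dplyr::bind_rows(rows)
}

#' One-row summary of a social network
#'
#' @param x A `social_network`.
#' @param ... Unused.
#' @return A tibble with vertex, edge and community counts and directedness.
#' @method glance social_network
#' @export
glance.social_network <- function(x, ...) {
  tibble::tibble(
    n_vertices = length(x$graph$vertices),
    n_edges = nrow(x$graph$edges),
    n_communities = length(x$labels),
    directed = x$graph$directed
  )
}

#' @export
as_igraph.social_network <- function(x, ...) {
  ig <- as_igraph(x$graph)
  igraph::set_vertex_attr(
    ig, "communities",
    value = vapply(x$membership, paste, character(1), collapse = ";")
  )
}
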