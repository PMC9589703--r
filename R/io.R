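# Network I/O: edge list + membership table (CSV or whitespace), GraphML with
# a `communities` vertex attribute, and a JSON round-trip format mirroring the
# social_network fields exactly.

#' Read a social network from an edge list and a membership table
#'
#' The edge source holds one edge per row, comma- or whitespace-separated,
#' with an optional `from,to` header. The membership source is a two-column
#' CSV `vertex,labels` where `labels` is a semicolon-separated list of
#' community names (empty field = member of no community). Vertices appearing
#' only in the membership table become isolated vertices. Duplicate edges
#' (including both orientations of an undirected edge) collapse to one with a
#' warning.
#'
#' @param edge_source Path to the edge list.
#' @param membership_source Path to the membership table, or `NULL` for a
#'   network without community assignments.
#' @param directed Logical; read edges as directed?
#' @param strict If `TRUE`, an edge endpoint not declared in the membership
#'   table is an error rather than an implicitly added vertex.
#' @return A `social_network`.
#' @export
read_network <- function(edge_source, membership_source = NULL,
                         directed = FALSE, strict = FALSE) {
  em <- read_edge_rows(edge_source)
  membership <- if (is.null(membership_source)) {
    list()
  } else {
    mt <- readr::read_csv(membership_source, col_types = readr::cols(
      vertex = readr::col_character(), labels = readr::col_character()
    ))
    stats::setNames(lapply(mt$labels, parse_label_field),
                    as.character(mt$vertex))
  }
  if (strict && length(membership) > 0) {
    undeclared <- setdiff(unique(as.vector(em)), names(membership))
    if (length(undeclared) > 0) {
      stop("edge list references vertices absent from the membership table: ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }
  g <- graph(edges = em, directed = directed)
  social_network(g, membership = membership)
}

# parse an edge file into a 2-column character matrix; rows that do not have
# exactly two fields are reported with their line number
read_edge_rows <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) return(matrix(character(), ncol = 2))
  sep_split <- function(x) {
    if (grepl(",", x, fixed = TRUE)) {
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(trimws(x), "[[:space:]]+")[[1]]
    }
  }
  fields <- lapply(lines, sep_split)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop("malformed edge row at line ", bad[[1]], ": ", lines[[bad[[1]]]],
         call. = FALSE)
  }
  em <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  if (tolower(em[1, 1]) == "from" && tolower(em[1, 2]) == "to") {
    em <- em[-1, , drop = FALSE]
  }
  em
}

#' Write a social network as an edge list and a membership table
#'
#' Inverse of [read_network()]: emits a `from,to` edge CSV (directed edges
#' preserve orientation) and a `vertex,labels` membership CSV with one row per
#' vertex, labels semicolon-separated. Empty networks produce header-only
#' files.
#'
#' @param net A `social_network`.
#' @param edge_dest,membership_dest Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edge_dest, membership_dest) {
  stopifnot(inherits(net, "social_network"))
  readr::write_csv(graph_edges(net$graph), edge_dest)
  readr::write_csv(
    tibble::tibble(
      vertex = names(net$membership),
      labels = vapply(net$membership, paste, character(1), collapse = ";")
    ),
    membership_dest
  )
  invisible(c(edge_dest, membership_dest))
}

#' Read and write social networks as GraphML
#'
#' Community memberships travel in a `communities` string vertex attribute
#' (semicolon-separated labels).
#'
#' @param net A `social_network`.
#' @param path GraphML file path.
#' @return `read_network_graphml()`: a `social_network`;
#'   `write_network_graphml()`: `path` invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vs <- igraph::vertex_attr(ig, "name")
  em <- igraph::as_edgelist(ig, names = TRUE)
  comm <- if ("communities" %in% igraph::vertex_attr_names(ig)) {
    igraph::vertex_attr(ig, "communities")
  } else {
    rep("", length(vs))
  }
  social_network(
    graph(vertices = vs, edges = em, directed = igraph::is_directed(ig)),
    membership = stats::setNames(lapply(comm, parse_label_field), vs)
  )
}

#' Read and write social networks as JSON
#'
#' The JSON format mirrors the type's fields exactly: `directed`, `vertices`,
#' `edges` (records of `from`/`to`), `labels` and `membership` (vertex name to
#' label array).
#'
#' @param net A `social_network`.
#' @param path JSON file path.
#' @return `read_network_json()`: a `social_network`;
#'   `write_network_json()`: `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "social_network"))
  x <- list(
    directed = net$graph$directed,
    vertices = net$graph$vertices,
    edges = lapply(seq_len(nrow(net$graph$edges)), function(i) {
      list(from = net$graph$edges[i, 1], to = net$graph$edges[i, 2])
    }),
    labels = net$labels,
    membership = lapply(net$membership, as.list)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  em <- if (length(x$edges) == 0) NULL else {
    matrix(unlist(lapply(x$edges, function(e) c(e$from, e$to))),
           ncol = 2, byrow = TRUE)
  }
  social_network(
    graph(vertices = unlist(x$vertices %||% list()), edges = em,
          directed = isTRUE(x$directed)),
    membership = lapply(x$membership, function(m) unlist(m) %||% character()),
    labels = unlist(x$labels %||% list())
  )
}

#' Read a school friendship excerpt in adjacency-matrix format
#'
#' Loader for the published text format of the 50-student school friendship
#' excerpt: a square 0/1 adjacency matrix (whitespace-separated, one student
#' per row) plus an attribute file with one row per student giving an alcohol
#' consumption score per wave (1 = never ... 5 = more than once a week).
#' Students scoring at or above `threshold` in the chosen wave column form the
#' `frequent` drinker community, the remainder the `infrequent` community.
#' Friendship nominations are symmetrised to undirected edges.
#'
#' @param adjacency_path Path to the adjacency matrix for the wave of
#'   interest.
#' @param alcohol_path Path to the alcohol attribute file.
#' @param alcohol_column Which column (wave) of the attribute file to use.
#' @param threshold Minimum score counted as a frequent drinker.
#' @return A `social_network` with communities `frequent` and `infrequent`
#'   partitioning the vertices.
#' @export
read_school_excerpt <- function(adjacency_path, alcohol_path,
                                alcohol_column = 2, threshold = 4) {
  adj <- as.matrix(utils::read.table(adjacency_path))
  n <- nrow(adj)
  stopifnot(ncol(adj) == n)
  alc <- utils::read.table(alcohol_path)
  stopifnot(nrow(alc) == n, alcohol_column <= ncol(alc))
  score <- as.numeric(alc[[alcohol_column]])
  vs <- sprintf("s%02d", seq_len(n))
  pairs <- which(adj != 0, arr.ind = TRUE)
  em <- if (nrow(pairs) == 0) NULL else cbind(vs[pairs[, 1]], vs[pairs[, 2]])
  membership <- stats::setNames(
    as.list(ifelse(score >= threshold, "frequent", "infrequent")), vs
  )
  suppressWarnings(  # symmetrised nominations collapse as duplicates
    social_network(graph(vertices = vs, edges = em, directed = FALSE),
                   membership = membership,
                   labels = c("frequent", "infrequent"))
  )
}
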