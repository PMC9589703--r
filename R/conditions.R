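# The relationship calculus: composing the component-profile map with the
# binary relations, the condition vocabulary, and the necessary-and-sufficient
# condition sets characterising each topological relationship.

RELATIONSHIP_NAMES <- c("disjoint", "a-in-b", "b-in-a", "equal",
                        "partial-overlap", "touch")

CONDITION_KINDS <- c("empty-intersection", "nonempty-intersection",
                     "empty-subtraction", "nonempty-subtraction",
                     "all-singletons", "single-component-union",
                     "touch-bound", "coverage-all")

condition_arity <- function(kind) {
  switch(kind,
         "all-singletons" = 1L,
         "coverage-all" = 1L,
         2L)
}

#' Component profile of a binary relation between two communities
#'
#' Applies the component-profile map to the intersection (`"I"`), union
#' (`"U"`) or subtraction (`"S"`) of two community subgraphs. Intersection and
#' union profiles are symmetric in the two communities; subtraction uses the
#' argument order (`a` minus `b`).
#'
#' Because communities are vertex-induced subgraphs, the intersection and
#' subtraction of the two subgraphs coincide with the induced subgraphs on the
#' intersection and difference of the member sets. The union is taken as the
#' induced subgraph on the union of the member sets: it therefore retains
#' edges of the network joining a member of one community to a member of the
#' other, which a bare set-union of the two subgraphs would drop. Those
#' connecting edges are exactly what the touch characterisation counts, so
#' this is the reading under which the touch conditions are necessary and
#' sufficient; the two readings agree whenever no cross-community edge exists.
#'
#' @param net A `social_network`.
#' @param relation One of `"I"`, `"U"`, `"S"`.
#' @param a,b Community labels.
#' @return A `component_profile`.
#' @examples
#' net <- fixture_network("fig4")
#' profile_relation(net, "I", "blue", "red")  # {2, 1, 1}
#' profile_relation(net, "S", "red", "blue")  # {1}
#' @export
profile_relation <- function(net, relation = c("I", "U", "S"), a, b) {
  relation <- match.arg(relation)
  g <- switch(relation,
              I = graph_intersect(community_subgraph(net, a),
                                  community_subgraph(net, b)),
              U = induced_on(net, union(community_members(net, a),
                                        community_members(net, b))),
              S = graph_subtract(community_subgraph(net, a),
                                 community_subgraph(net, b)))
  component_profile(g)
}

# induced subgraph of the network on an arbitrary vertex subset
induced_on <- function(net, vertices) {
  vertices <- sort(unique(vertices))
  em <- net$graph$edges
  keep <- em[, 1] %in% vertices & em[, 2] %in% vertices
  new_graph(vertices, em[keep, , drop = FALSE], net$graph$directed)
}

#' Construct a relationship condition
#'
#' A condition is one clause of a necessary-and-sufficient characterisation of
#' a topological relationship, phrased over component profiles:
#'
#' * `empty-intersection(a, b)` / `nonempty-intersection(a, b)`: the profile of
#'   the intersection of the two community subgraphs is (non-)empty.
#' * `empty-subtraction(a, b)` / `nonempty-subtraction(a, b)`: the profile of
#'   `a` minus `b` is (non-)empty; order matters.
#' * `all-singletons(a)`: every component of community `a` has size one.
#' * `single-component-union(a, b)`: the union of the two communities is one
#'   connected component.
#' * `touch-bound(a, b)`: the union has strictly fewer components than the two
#'   communities have separately, i.e. at least one edge joins them.
#' * `coverage-all(b)`: every vertex of the network shares at least one vertex
#'   between its ego community and community `b` — each individual belongs to
#'   `b` or is directly connected to a member of `b`.
#'
#' @param kind One of the condition kinds above.
#' @param ... One or two community labels, matching the kind's arity.
#' @return An object of class `ct_condition`.
#' @export
condition <- function(kind, ...) {
  kind <- match.arg(kind, CONDITION_KINDS)
  communities <- as.character(unlist(list(...), use.names = FALSE))
  if (length(communities) != condition_arity(kind)) {
    stop(sprintf("condition kind '%s' takes %d communit%s, got %d", kind,
                 condition_arity(kind),
                 if (condition_arity(kind) == 1) "y" else "ies",
                 length(communities)),
         call. = FALSE)
  }
  structure(list(kind = kind, communities = communities),
            class = "ct_condition")
}

#' @export
print.ct_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.ct_condition <- function(x, ...) {
  sprintf("%s(%s)", x$kind, paste(x$communities, collapse = ", "))
}

#' Construct a condition set
#'
#' A conjunction of conditions; an intervention target is a condition set that
#' must hold in the post-intervention network.
#'
#' @param ... `ct_condition` objects (or a single list of them).
#' @return An object of class `ct_condition_set`.
#' @export
condition_set <- function(...) {
  conds <- list(...)
  if (length(conds) == 1 && is.list(conds[[1]]) &&
      !inherits(conds[[1]], "ct_condition")) {
    conds <- conds[[1]]
  }
  ok <- vapply(conds, inherits, logical(1), "ct_condition")
  if (!all(ok)) stop("all elements must be conditions", call. = FALSE)
  structure(unname(conds), class = "ct_condition_set")
}

#' @export
print.ct_condition_set <- function(x, ...) {
  cat(sprintf("<condition set: %d condition(s)>\n", length(x)))
  for (c_ in x) cat("  ", format(c_), "\n", sep = "")
  invisible(x)
}

#' Evaluate a condition on a social network
#'
#' @param net A `social_network`.
#' @param cond A `ct_condition`.
#' @return Logical scalar.
#' @export
evaluate_condition <- function(net, cond) {
  stopifnot(inherits(net, "social_network"), inherits(cond, "ct_condition"))
  cs <- cond$communities
  for (l in cs) check_label(net, l)
  switch(
    cond$kind,
    "empty-intersection" =
      length(profile_relation(net, "I", cs[1], cs[2])) == 0,
    "nonempty-intersection" =
      length(profile_relation(net, "I", cs[1], cs[2])) > 0,
    "empty-subtraction" =
      length(profile_relation(net, "S", cs[1], cs[2])) == 0,
    "nonempty-subtraction" =
      length(profile_relation(net, "S", cs[1], cs[2])) > 0,
    "all-singletons" =
      all(component_profile(community_subgraph(net, cs[1])) == 1L),
    "single-component-union" =
      length(profile_relation(net, "U", cs[1], cs[2])) == 1,
    "touch-bound" = {
      pu <- profile_relation(net, "U", cs[1], cs[2])
      pa <- component_profile(community_subgraph(net, cs[1]))
      pb <- component_profile(community_subgraph(net, cs[2]))
      length(pu) < length(pa) + length(pb)
    },
    "coverage-all" = {
      members <- community_members(net, cs[1])
      all(vapply(net$graph$vertices, function(v) {
        any(graph_vertices(ego_community(net, v)) %in% members)
      }, logical(1)))
    },
    stop("unknown condition kind: ", cond$kind, call. = FALSE)
  )
}

#' Evaluate every condition of a set
#'
#' @param net A `social_network`.
#' @param conds A `ct_condition_set` (or list of conditions).
#' @return A tibble with columns `condition` (formatted), `kind`,
#'   `communities` (list column) and `satisfied`.
#' @export
evaluate_conditions <- function(net, conds) {
  conds <- as_condition_set(conds)
  tibble::tibble(
    condition = vapply(conds, format, character(1)),
    kind = vapply(conds, function(c_) c_$kind, character(1)),
    communities = lapply(conds, function(c_) c_$communities),
    satisfied = vapply(conds, function(c_) evaluate_condition(net, c_),
                       logical(1))
  )
}

as_condition_set <- function(x) {
  if (inherits(x, "ct_condition_set")) return(x)
  if (inherits(x, "ct_condition")) return(condition_set(x))
  if (is.list(x)) return(condition_set(x))
  stop("expected a condition set", call. = FALSE)
}

#' Necessary and sufficient conditions for a named topological relationship
#'
#' Expands a relationship name into its characterising condition set over two
#' communities `a` and `b`:
#'
#' | relationship      | conditions |
#' |-------------------|------------|
#' | `disjoint`        | empty-intersection(a, b) |
#' | `a-in-b`          | empty-subtraction(a, b) |
#' | `b-in-a`          | empty-subtraction(b, a) |
#' | `equal`           | empty-subtraction(a, b), empty-subtraction(b, a) |
#' | `partial-overlap` | nonempty-intersection(a, b), nonempty-subtraction(a, b), nonempty-subtraction(b, a) |
#' | `touch`           | empty-intersection(a, b), touch-bound(a, b) |
#'
#' @param relationship One of the names above.
#' @param a,b Community labels.
#' @return A `ct_condition_set`.
#' @export
relationship_conditions <- function(relationship, a, b) {
  relationship <- match.arg(relationship, RELATIONSHIP_NAMES)
  switch(
    relationship,
    "disjoint" = condition_set(condition("empty-intersection", a, b)),
    "a-in-b" = condition_set(condition("empty-subtraction", a, b)),
    "b-in-a" = condition_set(condition("empty-subtraction", b, a)),
    "equal" = condition_set(condition("empty-subtraction", a, b),
                            condition("empty-subtraction", b, a)),
    "partial-overlap" = condition_set(
      condition("nonempty-intersection", a, b),
      condition("nonempty-subtraction", a, b),
      condition("nonempty-subtraction", b, a)
    ),
    "touch" = condition_set(condition("empty-intersection", a, b),
                            condition("touch-bound", a, b))
  )
}

#' Classify the topological relationship between two communities
#'
#' Evaluates the characterising condition set of every named relationship and
#' returns all that hold. The relationships are not mutually exclusive: touch
#' implies disjoint, and equality implies containment both ways, so several
#' names can be returned together. Use [most_specific_relationship()] for a
#' single headline name.
#'
#' @param net A `social_network`.
#' @param a,b Community labels.
#' @return Character vector of satisfied relationship names.
#' @examples
#' net <- fixture_network("fig1a")
#' classify_relationship(net, "blue", "red")  # partial-overlap
#' @export
classify_relationship <- function(net, a, b) {
  stopifnot(inherits(net, "social_network"))
  check_label(net, a); check_label(net, b)
  sat <- vapply(RELATIONSHIP_NAMES, function(r) {
    conds <- relationship_conditions(r, a, b)
    all(vapply(conds, function(c_) evaluate_condition(net, c_), logical(1)))
  }, logical(1))
  RELATIONSHIP_NAMES[sat]
}

#' Most specific relationship among a set of satisfied names
#'
#' Applies the precedence equal > containment > touch > disjoint /
#' partial-overlap, collapsing the relationship names returned by
#' [classify_relationship()] to a single headline description.
#'
#' @param relationships Character vector of relationship names, or a
#'   `social_network` (then `a` and `b` must be given and classification runs
#'   first).
#' @param a,b Community labels, when a network is supplied.
#' @return A single relationship name, or `NA_character_` if none hold.
#' @export
most_specific_relationship <- function(relationships, a = NULL, b = NULL) {
  if (inherits(relationships, "social_network")) {
    relationships <- classify_relationship(relationships, a, b)
  }
  precedence <- c("equal", "a-in-b", "b-in-a", "touch", "disjoint",
                  "partial-overlap")
  hit <- precedence[precedence %in% relationships]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

# ---- serialisation -------------------------------------------------------

condition_set_to_list <- function(conds) {
  list(conditions = lapply(conds, function(c_) {
    list(kind = c_$kind, communities = as.list(c_$communities))
  }))
}

condition_set_from_list <- function(x, a = NULL, b = NULL) {
  if (!is.null(x$relationship)) {
    return(relationship_conditions(x$relationship,
                                   x$communities[[1]], x$communities[[2]]))
  }
  condition_set(lapply(x$conditions, function(e) {
    do.call(condition, c(list(e$kind), as.list(unlist(e$communities))))
  }))
}

#' Read and write condition sets
#'
#' Condition sets serialise to a small YAML/JSON schema: either a list of
#' `{kind, communities: [...]}` entries under `conditions:`, or the shorthand
#' `{relationship: <name>, communities: [a, b]}` which expands via
#' [relationship_conditions()].
#'
#' @param path File path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @param conds A `ct_condition_set`.
#' @return `read_conditions()` returns a `ct_condition_set`;
#'   `write_conditions()` returns `path` invisibly.
#' @export
read_conditions <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  condition_set_from_list(x)
}

#' @rdname read_conditions
#' @export
write_conditions <- function(conds, path) {
  conds <- as_condition_set(conds)
  x <- condition_set_to_list(conds)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
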