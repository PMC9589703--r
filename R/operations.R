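# Network edit operations (vertex removal, edge addition/removal, community
# reassignment) and domain-specific feasibility policies restricting which of
# them an intervention may use.

OP_TYPES <- c("remove_vertex", "add_edge", "remove_edge", "set_membership")

# shorthand used in serialised policies, after the operation symbols
OP_ALIASES <- c("V-" = "remove_vertex", "E+" = "add_edge",
                "E-" = "remove_edge", "CD" = "set_membership")

normalise_op_type <- function(x) {
  if (x %in% names(OP_ALIASES)) return(unname(OP_ALIASES[[x]]))
  match.arg(x, OP_TYPES)
}

#' Network edit operations
#'
#' The four atomic edits an intervention implementation is built from:
#'
#' * `op_remove_vertex(v)` deletes a vertex, its membership entry and every
#'   incident edge.
#' * `op_add_edge(from, to)` inserts an edge (which must be absent).
#' * `op_remove_edge(from, to)` deletes an existing edge.
#' * `op_set_membership(v, labels)` replaces a vertex's community label set
#'   (possibly with the empty set).
#'
#' @param v,from,to Vertex names. Edge endpoints must be distinct.
#' @param labels Character vector of community labels (may be empty).
#' @return An object of class `ct_operation`.
#' @export
op_remove_vertex <- function(v) {
  new_operation("remove_vertex", vertex = as.character(v))
}

#' @rdname op_remove_vertex
#' @export
op_add_edge <- function(from, to) {
  new_edge_op("add_edge", from, to)
}

#' @rdname op_remove_vertex
#' @export
op_remove_edge <- function(from, to) {
  new_edge_op("remove_edge", from, to)
}

#' @rdname op_remove_vertex
#' @export
op_set_membership <- function(v, labels = character()) {
  new_operation("set_membership", vertex = as.character(v),
                labels = sort(unique(as.character(labels))))
}

new_edge_op <- function(type, from, to) {
  from <- as.character(from); to <- as.character(to)
  if (identical(from, to)) {
    stop("edge endpoints must be distinct", call. = FALSE)
  }
  new_operation(type, from = from, to = to)
}

new_operation <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "ct_operation")
}

#' @export
print.ct_operation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.ct_operation <- function(x, ...) {
  switch(x$type,
         remove_vertex = sprintf("remove_vertex(%s)", x$vertex),
         add_edge = sprintf("add_edge(%s, %s)", x$from, x$to),
         remove_edge = sprintf("remove_edge(%s, %s)", x$from, x$to),
         set_membership = sprintf("set_membership(%s, {%s})", x$vertex,
                                  paste(x$labels, collapse = ", ")))
}

# vertices an operation touches (used by feasibility guards)
operation_vertices <- function(op) {
  switch(op$type,
         remove_vertex = op$vertex,
         set_membership = op$vertex,
         c(op$from, op$to))
}

#' Apply a single edit operation to a social network
#'
#' Pure: returns an edited copy, the input network value is unchanged.
#' Preconditions are enforced strictly — removing an absent vertex or edge,
#' adding a present edge, or assigning an undeclared label is an error.
#' Planners, not this layer, are responsible for check-and-skip logic.
#'
#' @param net A `social_network`.
#' @param op A `ct_operation`.
#' @return The edited `social_network`.
#' @examples
#' net <- fixture_network("fig1a")
#' apply_operation(net, op_remove_vertex("c"))  # the fig1b network
#' @export
apply_operation <- function(net, op) {
  stopifnot(inherits(net, "social_network"), inherits(op, "ct_operation"))
  g <- net$graph
  switch(
    op$type,
    remove_vertex = {
      if (!(op$vertex %in% g$vertices)) {
        stop("cannot remove absent vertex: ", op$vertex, call. = FALSE)
      }
      vs <- setdiff(g$vertices, op$vertex)
      keep <- g$edges[, 1] != op$vertex & g$edges[, 2] != op$vertex
      net$graph <- new_graph(vs, g$edges[keep, , drop = FALSE], g$directed)
      net$membership[[op$vertex]] <- NULL
      net
    },
    add_edge = {
      check_op_vertices(g, op)
      em <- canonical_edges(matrix(c(op$from, op$to), ncol = 2), g$directed)
      if (edge_keys(em) %in% edge_keys(g$edges)) {
        stop(sprintf("edge (%s, %s) already present", op$from, op$to),
             call. = FALSE)
      }
      all_em <- rbind(g$edges, em)
      all_em <- all_em[order(all_em[, 1], all_em[, 2]), , drop = FALSE]
      net$graph <- new_graph(g$vertices, all_em, g$directed)
      net
    },
    remove_edge = {
      check_op_vertices(g, op)
      em <- canonical_edges(matrix(c(op$from, op$to), ncol = 2), g$directed)
      hit <- edge_keys(g$edges) %in% edge_keys(em)
      if (!any(hit)) {
        stop(sprintf("cannot remove absent edge (%s, %s)", op$from, op$to),
             call. = FALSE)
      }
      net$graph <- new_graph(g$vertices, g$edges[!hit, , drop = FALSE],
                             g$directed)
      net
    },
    set_membership = {
      if (!(op$vertex %in% g$vertices)) {
        stop("cannot reassign absent vertex: ", op$vertex, call. = FALSE)
      }
      bad <- setdiff(op$labels, net$labels)
      if (length(bad) > 0) {
        stop("undeclared community label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      net$membership[[op$vertex]] <- op$labels
      net
    }
  )
}

check_op_vertices <- function(g, op) {
  missing <- setdiff(c(op$from, op$to), g$vertices)
  if (length(missing) > 0) {
    stop("unknown vertex in edge operation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Apply an operation sequence left to right
#'
#' Folds [apply_operation()] over `ops`. The first failing operation aborts
#' the whole application with its position and reason; no partial result is
#' returned. An operation log (one record per step, with pre/post vertex and
#' edge counts) is attached to the result as attribute `"log"`.
#'
#' @param net A `social_network`.
#' @param ops A list of `ct_operation` objects (or an `intervention_plan`,
#'   whose `ops` are used).
#' @return The edited `social_network`, with a tibble log in `attr(, "log")`.
#' @export
apply_operations <- function(net, ops) {
  if (inherits(ops, "intervention_plan")) ops <- ops$ops
  if (inherits(ops, "ct_operation")) ops <- list(ops)
  log <- vector("list", length(ops))
  out <- net
  for (i in seq_along(ops)) {
    pre_v <- length(out$graph$vertices); pre_e <- nrow(out$graph$edges)
    out <- tryCatch(
      apply_operation(out, ops[[i]]),
      error = function(e) {
        stop(sprintf("operation %d (%s) failed: %s", i, format(ops[[i]]),
                     conditionMessage(e)), call. = FALSE)
      }
    )
    log[[i]] <- tibble::tibble(
      step = i, operation = format(ops[[i]]),
      pre_vertices = pre_v, pre_edges = pre_e,
      post_vertices = length(out$graph$vertices),
      post_edges = nrow(out$graph$edges)
    )
  }
  attr(out, "log") <- dplyr::bind_rows(log)
  out
}

#' Write an operation log as JSON lines
#'
#' @param net_or_log A network returned by [apply_operations()] (whose log
#'   attribute is used) or the log tibble itself.
#' @param path Destination file; one JSON record per applied operation.
#' @return `path`, invisibly.
#' @export
write_operation_log <- function(net_or_log, path) {
  log <- if (is.data.frame(net_or_log)) net_or_log else attr(net_or_log, "log")
  if (is.null(log)) stop("no operation log found", call. = FALSE)
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- feasibility policies ------------------------------------------------

#' Feasibility policies
#'
#' A feasibility policy declares which edit operations an intervention may
#' use, mirroring real-world constraints (e.g. undercover agents may only cut
#' ties among themselves). A policy is an ordered list of rules; an operation
#' is feasible iff some rule matches its type and the rule's guard holds. A
#' policy with no rules permits nothing.
#'
#' Guards are membership predicates over the operation's own vertices:
#' `all_endpoints_in` / `any_endpoint_in` require all (any) of the operation's
#' vertices to belong to the named community. A guard may also be an arbitrary
#' predicate `function(op, net)`, though such rules do not serialise. A
#' free-text `realisation` note (how the edit maps to a real-world action) may
#' be attached for reporting.
#'
#' @param op Operation type: one of `"remove_vertex"`, `"add_edge"`,
#'   `"remove_edge"`, `"set_membership"` or the shorthand `"V-"`, `"E+"`,
#'   `"E-"`, `"CD"`.
#' @param all_endpoints_in,any_endpoint_in Community label the operation's
#'   vertices must (all / at least one) belong to; `NULL` for no constraint.
#' @param guard Optional predicate `function(op, net)`.
#' @param realisation Optional free-text note.
#' @param ... `policy_rule` objects for `feasibility_policy()`.
#' @return `policy_rule()`: a rule; `feasibility_policy()`: a policy;
#'   `allow_all_policy()`: a policy permitting every operation type
#'   unconditionally.
#' @examples
#' agents_only <- feasibility_policy(
#'   policy_rule("E-", all_endpoints_in = "red"),
#'   policy_rule("CD", all_endpoints_in = "red"),
#'   policy_rule("E+", any_endpoint_in = "red")
#' )
#' @export
policy_rule <- function(op, all_endpoints_in = NULL, any_endpoint_in = NULL,
                        guard = NULL, realisation = NULL) {
  structure(
    list(op = normalise_op_type(op), all_endpoints_in = all_endpoints_in,
         any_endpoint_in = any_endpoint_in, guard = guard,
         realisation = realisation),
    class = "ct_policy_rule"
  )
}

#' @rdname policy_rule
#' @export
feasibility_policy <- function(...) {
  rules <- list(...)
  if (length(rules) == 1 && is.list(rules[[1]]) &&
      !inherits(rules[[1]], "ct_policy_rule")) {
    rules <- rules[[1]]
  }
  ok <- vapply(rules, inherits, logical(1), "ct_policy_rule")
  if (!all(ok)) stop("all arguments must be policy rules", call. = FALSE)
  structure(unname(rules), class = "ct_policy")
}

#' @rdname policy_rule
#' @export
allow_all_policy <- function() {
  feasibility_policy(lapply(OP_TYPES, policy_rule))
}

#' @export
print.ct_policy <- function(x, ...) {
  cat(sprintf("<feasibility policy: %d rule(s)>\n", length(x)))
  for (r in x) {
    g <- if (!is.null(r$all_endpoints_in)) {
      sprintf(" if all endpoints in '%s'", r$all_endpoints_in)
    } else if (!is.null(r$any_endpoint_in)) {
      sprintf(" if any endpoint in '%s'", r$any_endpoint_in)
    } else if (!is.null(r$guard)) " if <custom guard>" else ""
    cat("  allow ", r$op, g, "\n", sep = "")
  }
  invisible(x)
}

#' Is an operation feasible under a policy?
#'
#' @param policy A `ct_policy`.
#' @param op A `ct_operation`.
#' @param net The `social_network` the operation would be applied to (guards
#'   inspect current memberships).
#' @return Logical scalar.
#' @export
is_feasible <- function(policy, op, net) {
  stopifnot(inherits(policy, "ct_policy"), inherits(op, "ct_operation"))
  for (r in policy) {
    if (r$op != op$type) next
    if (rule_guard_holds(r, op, net)) return(TRUE)
  }
  FALSE
}

rule_guard_holds <- function(rule, op, net) {
  vs <- operation_vertices(op)
  in_comm <- function(label) {
    vapply(vs, function(v) {
      m <- net$membership[[v]]
      !is.null(m) && label %in% m
    }, logical(1))
  }
  if (!is.null(rule$all_endpoints_in) &&
      !all(in_comm(rule$all_endpoints_in))) return(FALSE)
  if (!is.null(rule$any_endpoint_in) &&
      !any(in_comm(rule$any_endpoint_in))) return(FALSE)
  if (!is.null(rule$guard) && !isTRUE(rule$guard(op, net))) return(FALSE)
  TRUE
}

#' Read and write feasibility policies as YAML
#'
#' Rules serialise as entries like
#' `{op: "E-", require: {all_endpoints_in: red}, realisation: "..."}` under
#' `rules:`. Custom function guards are not serialisable and raise an error.
#'
#' @param path YAML file path.
#' @param policy A `ct_policy`.
#' @return `read_policy()`: a `ct_policy`; `write_policy()`: `path` invisibly.
#' @export
read_policy <- function(path) {
  x <- yaml::read_yaml(path)
  feasibility_policy(lapply(x$rules, function(e) {
    req <- e$require %||% list()
    policy_rule(e$op,
                all_endpoints_in = req$all_endpoints_in,
                any_endpoint_in = req$any_endpoint_in,
                realisation = e$realisation)
  }))
}

#' @rdname read_policy
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "ct_policy"))
  rules <- lapply(policy, function(r) {
    if (!is.null(r$guard)) {
      stop("policies with function guards cannot be serialised",
           call. = FALSE)
    }
    out <- list(op = r$op)
    req <- list()
    if (!is.null(r$all_endpoints_in)) req$all_endpoints_in <- r$all_endpoints_in
    if (!is.null(r$any_endpoint_in)) req$any_endpoint_in <- r$any_endpoint_in
    if (length(req) > 0) out$require <- req
    if (!is.null(r$realisation)) out$realisation <- r$realisation
    out
  })
  yaml::write_yaml(list(rules = rules), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
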