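# Intervention planners: compile a desired topological relationship (a
# condition set) into a sequence of feasible edit operations, and verify the
# conditions after application. Each planner mirrors one of the worked
# intervention algorithms: separation, fragmentation, infiltration,
# influence-based containment, ego-network coverage.

new_intervention_plan <- function(ops, target, strategy, seed = NULL,
                                  diffusion = NULL) {
  structure(
    list(ops = ops, target = target, strategy = strategy, seed = seed,
         diffusion = diffusion),
    class = "intervention_plan"
  )
}

#' @export
print.intervention_plan <- function(x, ...) {
  cat(sprintf("<intervention plan: strategy '%s', %d operation(s)>\n",
              x$strategy, length(x$ops)))
  for (op in x$ops) cat("  ", format(op), "\n", sep = "")
  cat("target:\n")
  for (c_ in x$target) cat("  ", format(c_), "\n", sep = "")
  if (!is.null(x$diffusion)) {
    cat(sprintf("requires influence propagation within '%s' adopting {%s}\n",
                x$diffusion$within,
                paste(x$diffusion$adopt, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an intervention plan into an operation tibble
#'
#' @param x An `intervention_plan`.
#' @param ... Unused.
#' @return A tibble with one row per operation: `step`, `type`, `vertex`,
#'   `from`, `to`, `labels` (list column).
#' @method tidy intervention_plan
#' @export
tidy.intervention_plan <- function(x, ...) {
  if (length(x$ops) == 0) {
    return(tibble::tibble(step = integer(), type = character(),
                          vertex = character(), from = character(),
                          to = character(), labels = list()))
  }
  dplyr::bind_rows(lapply(seq_along(x$ops), function(i) {
    op <- x$ops[[i]]
    tibble::tibble(
      step = i, type = op$type,
      vertex = op$vertex %||% NA_character_,
      from = op$from %||% NA_character_,
      to = op$to %||% NA_character_,
      labels = list(op$labels %||% NULL)
    )
  }))
}

#' One-row summary of an intervention plan
#'
#' @param x An `intervention_plan`.
#' @param ... Unused.
#' @return A tibble with strategy, operation count, target size, seed and
#'   whether influence propagation is required to reach the target.
#' @method glance intervention_plan
#' @export
glance.intervention_plan <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_ops = length(x$ops),
    n_conditions = length(x$target),
    seed = x$seed %||% NA_integer_,
    needs_diffusion = !is.null(x$diffusion)
  )
}

# error raised when a planner needs an operation variant the policy forbids
infeasible_plan_error <- function(variants, detail = NULL) {
  msg <- paste0("plan infeasible: policy does not permit required operation ",
                "variant(s): ", paste(unique(variants), collapse = ", "))
  if (!is.null(detail)) msg <- paste0(msg, "\n", detail)
  stop(errorCondition(msg, class = c("commtopo_infeasible_plan", "error",
                                     "condition")))
}

check_ops_feasible <- function(policy, ops, net) {
  bad <- vapply(ops, function(op) !is_feasible(policy, op, net), logical(1))
  if (any(bad)) {
    infeasible_plan_error(
      vapply(ops[bad], function(op) op$type, character(1))
    )
  }
  invisible(TRUE)
}

# run code under a temporary RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Plan: make two communities disjoint
#'
#' Targets `empty-intersection(a, b)`. The `remove-vertex` strategy removes
#' every vertex shared by the two communities; the `reassign-membership`
#' strategy instead strips label `b` from each shared vertex's membership.
#' Shared vertices are processed in lexicographic order; already-disjoint
#' communities yield an empty plan.
#'
#' @param net A `social_network`.
#' @param a,b Community labels.
#' @param strategy `"remove-vertex"` or `"reassign-membership"`.
#' @param policy A `ct_policy`; every emitted operation must be feasible,
#'   otherwise an infeasibility error names the offending variant.
#' @return An `intervention_plan`.
#' @examples
#' plan_disjoint(fixture_network("fig1a"), "blue", "red")
#' @export
plan_disjoint <- function(net, a, b,
                          strategy = c("remove-vertex", "reassign-membership"),
                          policy = allow_all_policy()) {
  strategy <- match.arg(strategy)
  check_label(net, a); check_label(net, b)
  shared <- graph_vertices(
    graph_intersect(community_subgraph(net, a), community_subgraph(net, b))
  )
  ops <- if (strategy == "remove-vertex") {
    lapply(shared, op_remove_vertex)
  } else {
    lapply(shared, function(v) {
      op_set_membership(v, setdiff(net$membership[[v]], b))
    })
  }
  check_ops_feasible(policy, ops, net)
  new_intervention_plan(
    ops, condition_set(condition("empty-intersection", a, b)),
    strategy = paste0("disjoint/", strategy)
  )
}

#' Plan: fragment a community into singletons
#'
#' Removes every edge internal to community `a` (lexicographic order), so that
#' each member ends up in its own connected component. Intended for use when
#' `a` is already disjoint from the other community of interest: with `other`
#' supplied the target is the condition pair all-singletons(`a`) and
#' empty-intersection(`a`, `other`); otherwise the target is
#' all-singletons(`a`) alone.
#'
#' @inheritParams plan_disjoint
#' @param a Community to fragment.
#' @param other Optional second community for the disjointness clause of the
#'   target.
#' @return An `intervention_plan`.
#' @examples
#' plan_atomize(fixture_network("fig5a"), "red", other = "blue")
#' @export
plan_atomize <- function(net, a, other = NULL,
                         policy = allow_all_policy()) {
  check_label(net, a)
  if (!is.null(other)) check_label(net, other)
  em <- community_subgraph(net, a)$edges
  ops <- lapply(seq_len(nrow(em)), function(i) op_remove_edge(em[i, 1],
                                                              em[i, 2]))
  check_ops_feasible(policy, ops, net)
  target <- if (is.null(other)) {
    condition_set(condition("all-singletons", a))
  } else {
    condition_set(condition("all-singletons", a),
                  condition("empty-intersection", a, other))
  }
  new_intervention_plan(ops, target, strategy = "atomize")
}

#' Plan: infiltrate one community into another
#'
#' Compiles the infiltration intervention: every member of `a` additionally
#' joins community `b`, and an edge is added between each pair of (original)
#' `a` and `b` members not already adjacent. Membership snapshots are taken
#' before any edit, so the pair loop never adds edges inside `a`. Assumes `a`
#' is initially fragmented and disjoint from `b`; the target is the condition
#' triple all-singletons(`a`), empty-subtraction(`a`, `b`) and
#' single-component-union(`a`, `b`).
#'
#' @inheritParams plan_disjoint
#' @param a Infiltrating community (e.g. undercover agents).
#' @param b Host community (e.g. the group to infiltrate).
#' @return An `intervention_plan`.
#' @examples
#' plan_infiltrate(fixture_network("fig5b"), "red", "blue")
#' @export
plan_infiltrate <- function(net, a, b, policy = allow_all_policy()) {
  check_label(net, a); check_label(net, b)
  va <- community_members(net, a)   # snapshots before any edit
  vb <- community_members(net, b)
  ops <- lapply(va, function(v) {
    op_set_membership(v, union(net$membership[[v]], b))
  })
  existing <- edge_keys(net$graph$edges)
  added <- character()
  for (v in va) {
    for (v2 in vb) {
      if (identical(v, v2)) next
      key <- edge_keys(canonical_edges(matrix(c(v, v2), ncol = 2),
                                       net$graph$directed))
      if (key %in% existing || key %in% added) next
      added <- c(added, key)
      ops[[length(ops) + 1]] <- op_add_edge(v, v2)
    }
  }
  check_ops_feasible(policy, ops, net)
  new_intervention_plan(
    ops,
    condition_set(condition("all-singletons", a),
                  condition("empty-subtraction", a, b),
                  condition("single-component-union", a, b)),
    strategy = "infiltrate"
  )
}

# greedy minimum in-dominating set of community `a`: every member outside the
# seed set has an in-edge from a seed; a vertex always covers itself
greedy_in_dominating_set <- function(net, a) {
  members <- community_members(net, a)
  if (length(members) == 0) return(character())
  em <- net$graph$edges
  intra <- em[em[, 1] %in% members & em[, 2] %in% members, , drop = FALSE]
  covers <- stats::setNames(lapply(members, function(v) {
    sort(unique(c(v, intra[intra[, 1] == v, 2])))
  }), members)
  uncovered <- members
  seeds <- character()
  while (length(uncovered) > 0) {
    gain <- vapply(members, function(v) sum(covers[[v]] %in% uncovered),
                   integer(1))
    best <- members[which.max(gain)]  # which.max takes the first (lexicographic) maximiser
    seeds <- c(seeds, best)
    uncovered <- setdiff(uncovered, covers[[best]])
  }
  sort(seeds)
}

#' Plan: contain a community via influential seeds and assimilative influence
#'
#' Selects a seed set of highly influential members of `a` — a greedy minimum
#' in-dominating set, so every other member of `a` receives a directed
#' influence edge from some seed — and reassigns each seed's membership to
#' additionally include `b`. The target, `empty-subtraction(a, b)` (community
#' `a` contained in `b`), is achieved only after assimilative influence
#' propagates the adopted membership through the community; the plan records
#' this dependency and [verify_plan()] runs [propagate_influence()] before
#' evaluating the target.
#'
#' @inheritParams plan_disjoint
#' @param a Community whose members should end up in `b` (seeds chosen here).
#' @param b Community to be adopted.
#' @return An `intervention_plan` with a diffusion dependency.
#' @examples
#' plan_influence_containment(fixture_network("fig7a"), "red", "blue")
#' @export
plan_influence_containment <- function(net, a, b,
                                       policy = allow_all_policy()) {
  check_label(net, a); check_label(net, b)
  if (!net$graph$directed) {
    stop("influence containment requires a directed network ",
         "(influence edges are directed)", call. = FALSE)
  }
  seeds <- greedy_in_dominating_set(net, a)
  ops <- lapply(seeds, function(v) {
    op_set_membership(v, union(net$membership[[v]], b))
  })
  check_ops_feasible(policy, ops, net)
  new_intervention_plan(
    ops, condition_set(condition("empty-subtraction", a, b)),
    strategy = "influence-containment",
    diffusion = list(within = a, adopt = b)
  )
}

#' Plan: guarantee every vertex a neighbour in a covering community
#'
#' For each vertex of the network (lexicographic order) whose ego community
#' shares no vertex with community `covering`, adds one edge from that vertex
#' to a member of `covering` selected uniformly at random. The target is
#' `coverage-all(covering)`: every individual either belongs to the covering
#' community or is directly connected to one of its members (e.g. every
#' student gains an infrequent-drinker friend). The plan length — the number
#' of initially uncovered vertices — does not depend on the seed; only the
#' chosen partners do.
#'
#' @inheritParams plan_disjoint
#' @param covering The covering community; must be non-empty.
#' @param seed Optional integer seed driving the random partner choice,
#'   recorded in the plan.
#' @return An `intervention_plan`.
#' @export
plan_coverage <- function(net, covering, seed = NULL,
                          policy = allow_all_policy()) {
  check_label(net, covering)
  members <- community_members(net, covering)
  if (length(members) == 0) {
    stop("covering community '", covering, "' has no members", call. = FALSE)
  }
  uncovered <- net$graph$vertices[
    !vapply(net$graph$vertices, function(v) {
      any(graph_vertices(ego_community(net, v)) %in% members)
    }, logical(1))
  ]
  ops <- with_local_seed(seed, {
    lapply(uncovered, function(v) {
      partner <- if (length(members) == 1) members else sample(members, 1)
      op_add_edge(v, partner)
    })
  })
  check_ops_feasible(policy, ops, net)
  new_intervention_plan(
    ops, condition_set(condition("coverage-all", covering)),
    strategy = "coverage", seed = seed
  )
}

#' Apply a plan and verify its target conditions
#'
#' Applies the plan's operations to a copy of the network (the input value is
#' never modified), runs influence propagation first-class when the plan
#' records that dependency, then evaluates every target condition on the
#' resulting network.
#'
#' @param net A `social_network` the plan applies to.
#' @param plan An `intervention_plan`.
#' @return A `verification_report`: `satisfied` (all conditions hold),
#'   `per_condition` (tibble of individual outcomes), `summary` (vertex/edge
#'   counts and, for two-community targets, the relationship classification),
#'   `failure` (`NULL`, or the failing operation's index and reason), and
#'   `network` (the post-intervention network, `NULL` on failure).
#' @export
verify_plan <- function(net, plan) {
  stopifnot(inherits(net, "social_network"),
            inherits(plan, "intervention_plan"))
  result <- tryCatch(apply_operations(net, plan$ops), error = identity)
  if (inherits(result, "error")) {
    msg <- conditionMessage(result)
    idx <- as.integer(sub("^operation (\\d+) .*", "\\1", msg))
    per <- evaluate_conditions(net, plan$target)
    per$satisfied <- FALSE
    return(new_verification_report(
      satisfied = FALSE, per_condition = per, network = NULL,
      failure = list(index = idx, message = msg), plan = plan
    ))
  }
  if (!is.null(plan$diffusion)) {
    result <- propagate_influence(result, plan$diffusion$within,
                                  plan$diffusion$adopt)$final
  }
  per <- evaluate_conditions(result, plan$target)
  new_verification_report(
    satisfied = all(per$satisfied), per_condition = per, network = result,
    failure = NULL, plan = plan
  )
}

new_verification_report <- function(satisfied, per_condition, network,
                                    failure, plan) {
  labs <- unique(unlist(lapply(plan$target, function(c_) c_$communities)))
  summary <- if (is.null(network)) {
    list(n_vertices = NA_integer_, n_edges = NA_integer_,
         classification = character())
  } else {
    cls <- if (length(labs) == 2) {
      classify_relationship(network, labs[1], labs[2])
    } else character()
    list(n_vertices = length(network$graph$vertices),
         n_edges = nrow(network$graph$edges), classification = cls)
  }
  structure(
    list(satisfied = satisfied, per_condition = per_condition,
         summary = summary, failure = failure, network = network),
    class = "verification_report"
  )
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification report: %s>\n",
              if (x$satisfied) "SATISFIED" else "NOT satisfied"))
  for (i in seq_len(nrow(x$per_condition))) {
    cat(sprintf("  [%s] %s\n",
                if (x$per_condition$satisfied[i]) "ok" else "FAIL",
                x$per_condition$condition[i]))
  }
  if (!is.null(x$failure)) {
    cat("application failed:", x$failure$message, "\n")
  } else if (length(x$summary$classification) > 0) {
    cat("resulting relationship:",
        paste(x$summary$classification, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy verification_report
#' @export
tidy.verification_report <- function(x, ...) x$per_condition

#' @method glance verification_report
#' @export
glance.verification_report <- function(x, ...) {
  tibble::tibble(
    satisfied = x$satisfied,
    n_conditions = nrow(x$per_condition),
    n_satisfied = sum(x$per_condition$satisfied),
    n_vertices = x$summary$n_vertices,
    n_edges = x$summary$n_edges,
    relationship = if (length(x$summary$classification) > 0) {
      most_specific_relationship(x$summary$classification)
    } else NA_character_
  )
}

# ---- strategy dispatcher -------------------------------------------------

# target name -> ordered strategy builders
planner_registry <- function(net, a, b, policy, seed) {
  list(
    "disjoint" = list(
      "remove-vertex" = function() {
        plan_disjoint(net, a, b, strategy = "remove-vertex", policy = policy)
      },
      "reassign-membership" = function() {
        plan_disjoint(net, a, b, strategy = "reassign-membership",
                      policy = policy)
      }
    ),
    "fragment" = list(
      "atomize" = function() plan_atomize(net, a, other = b, policy = policy)
    ),
    "a-in-b" = c(
      list("infiltrate" = function() plan_infiltrate(net, a, b,
                                                     policy = policy)),
      if (net$graph$directed) {
        list("influence-containment" = function() {
          plan_influence_containment(net, a, b, policy = policy)
        })
      }
    ),
    "coverage" = list(
      "coverage" = function() plan_coverage(net, b, seed = seed,
                                            policy = policy)
    )
  )
}

# map a condition set onto a registered target name
match_target_name <- function(target) {
  kinds <- sort(vapply(target, function(c_) c_$kind, character(1)))
  if (identical(kinds, "empty-intersection")) return("disjoint")
  if (identical(kinds, "empty-subtraction")) return("a-in-b")
  if (identical(kinds, "coverage-all")) return("coverage")
  if (identical(kinds, sort(c("all-singletons", "empty-intersection")))) {
    return("fragment")
  }
  if (identical(kinds, sort(c("all-singletons", "empty-subtraction",
                              "single-component-union")))) {
    return("a-in-b")
  }
  stop("no registered strategy can compile this condition set",
       call. = FALSE)
}

#' Plan an intervention for a named target relationship
#'
#' Dispatcher over the registered planners. The target may be a relationship
#' or objective name (`"disjoint"`, `"fragment"`, `"a-in-b"` /
#' `"contained"`, `"coverage"`) or a `ct_condition_set` expressible by one of
#' them. Every applicable strategy is tried in declared order; among those
#' whose required operation variants are feasible under `policy`, the plan
#' with the fewest operations wins, ties broken by declaration order.
#'
#' @param net A `social_network`.
#' @param target Relationship/objective name or `ct_condition_set`.
#' @param a,b Community labels (for `"coverage"`, `b` is the covering
#'   community).
#' @param policy A `ct_policy`.
#' @param seed Optional seed forwarded to stochastic planners.
#' @return An `intervention_plan`. If no strategy is feasible an error of
#'   class `commtopo_infeasible_plan` lists what was tried.
#' @examples
#' cd_only <- feasibility_policy(policy_rule("CD"))
#' plan_intervention(fixture_network("fig1a"), "disjoint", "blue", "red",
#'                   policy = cd_only)  # reassign-membership fallback
#' @export
plan_intervention <- function(net, target, a, b,
                              policy = allow_all_policy(), seed = NULL) {
  name <- if (inherits(target, "ct_condition_set") ||
              (is.list(target) && !is.character(target))) {
    match_target_name(as_condition_set(target))
  } else {
    t <- as.character(target)
    if (t %in% c("contained", "containment")) "a-in-b" else t
  }
  registry <- planner_registry(net, a, b, policy, seed)
  if (!(name %in% names(registry))) {
    stop("no registered strategy for target '", name, "'", call. = FALSE)
  }
  strategies <- registry[[name]]
  plans <- list()
  failures <- character()
  for (s in names(strategies)) {
    res <- tryCatch(strategies[[s]](), error = identity)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", s, conditionMessage(res)))
    } else {
      plans[[s]] <- res
    }
  }
  if (length(plans) == 0) {
    infeasible_plan_error(
      names(strategies),
      detail = paste("tried:", paste(failures, collapse = "; "))
    )
  }
  lengths_ <- vapply(plans, function(p) length(p$ops), integer(1))
  plans[[which.min(lengths_)]]  # which.min keeps declaration order on ties
}

# ---- plan serialisation --------------------------------------------------

op_to_record <- function(op) {
  rec <- list(type = op$type)
  for (f in c("vertex", "from", "to")) {
    if (!is.null(op[[f]])) rec[[f]] <- op[[f]]
  }
  if (op$type == "set_membership") rec$labels <- as.list(op$labels)
  rec
}

op_from_record <- function(rec) {
  switch(rec$type,
         remove_vertex = op_remove_vertex(rec$vertex),
         add_edge = op_add_edge(rec$from, rec$to),
         remove_edge = op_remove_edge(rec$from, rec$to),
         set_membership = op_set_membership(rec$vertex,
                                            unlist(rec$labels %||% list())),
         stop("unknown operation type: ", rec$type, call. = FALSE))
}

#' Read and write intervention plans as JSON
#'
#' Plans serialise to a JSON object holding the ordered operation records, the
#' target condition set, the producing strategy, the seed (if any) and any
#' influence-propagation dependency.
#'
#' @param plan An `intervention_plan`.
#' @param path JSON file path.
#' @return `write_plan()`: `path` invisibly; `read_plan()`: the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "intervention_plan"))
  x <- list(
    strategy = plan$strategy,
    seed = plan$seed,
    ops = lapply(plan$ops, op_to_record),
    target = condition_set_to_list(plan$target)$conditions,
    diffusion = plan$diffusion
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  new_intervention_plan(
    ops = lapply(x$ops, op_from_record),
    target = condition_set(lapply(x$target, function(e) {
      do.call(condition, c(list(e$kind), as.list(unlist(e$communities))))
    })),
    strategy = x$strategy,
    seed = x$seed,
    diffusion = if (!is.null(x$diffusion)) {
      list(within = x$diffusion$within,
           adopt = unlist(x$diffusion$adopt))
    }
  )
}
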