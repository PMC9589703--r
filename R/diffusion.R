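# Assimilative-influence propagation: adopted community memberships spread
# along directed influence edges inside a community until a fixpoint.

#' Propagate adopted community membership by assimilative influence
#'
#' Runs synchronous rounds of assimilative influence inside community
#' `within`: in each round, every member of `within` whose membership does not
#' yet include all of `adopt` but which has an in-neighbour in `within` whose
#' membership already does, gains the `adopt` labels. Adoption is monotone
#' (labels are only ever added), so the process reaches a fixpoint in at most
#' as many rounds as there are vertices. When the seeded members influence
#' every other member directly, a single round suffices.
#'
#' @param net A directed `social_network` whose edges model assimilative
#'   influence (source influences target).
#' @param within Community label confining the propagation; influence does not
#'   spill over to non-members.
#' @param adopt Character vector of labels adopted vertices gain (must be
#'   declared community types).
#' @return A `diffusion_result`: `final` (the post-propagation network),
#'   `rounds` (number of rounds until fixpoint) and `adopters_per_round`
#'   (list of pairwise-disjoint vertex sets, one per round).
#' @examples
#' net <- fixture_network("fig7a")
#' seeded <- apply_operation(net, op_set_membership("d", c("red", "blue")))
#' propagate_influence(seeded, within = "red", adopt = "blue")
#' @export
propagate_influence <- function(net, within, adopt) {
  stopifnot(inherits(net, "social_network"))
  if (!net$graph$directed) {
    stop("influence propagation requires a directed network; ",
         "model influence edges as directed", call. = FALSE)
  }
  check_label(net, within)
  adopt <- sort(unique(as.character(adopt)))
  bad <- setdiff(adopt, net$labels)
  if (length(bad) > 0) {
    stop("undeclared community label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  members <- community_members(net, within)
  em <- net$graph$edges
  intra <- em[em[, 1] %in% members & em[, 2] %in% members, , drop = FALSE]
  has_all <- function(v) all(adopt %in% net$membership[[v]])
  adopters_per_round <- list()
  repeat {
    carriers <- members[vapply(members, has_all, logical(1))]
    pending <- setdiff(members, carriers)
    influenced <- unique(intra[intra[, 1] %in% carriers, 2])
    new_adopters <- sort(intersect(pending, influenced))
    if (length(new_adopters) == 0) break
    for (v in new_adopters) {
      net$membership[[v]] <- sort(union(net$membership[[v]], adopt))
    }
    adopters_per_round[[length(adopters_per_round) + 1]] <- new_adopters
  }
  structure(
    list(final = net, rounds = length(adopters_per_round),
         adopters_per_round = adopters_per_round),
    class = "diffusion_result"
  )
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion result: %d round(s), %d adopter(s)>\n",
              x$rounds, sum(lengths(x$adopters_per_round))))
  for (i in seq_along(x$adopters_per_round)) {
    cat(sprintf("  round %d: %s\n", i,
                paste(x$adopters_per_round[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy adopters-per-round of a diffusion result
#'
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return A tibble with columns `round` and `vertex`, one row per adoption.
#' @method tidy diffusion_result
#' @export
tidy.diffusion_result <- function(x, ...) {
  if (x$rounds == 0) {
    return(tibble::tibble(round = integer(), vertex = character()))
  }
  dplyr::bind_rows(lapply(seq_along(x$adopters_per_round), function(i) {
    tibble::tibble(round = i, vertex = x$adopters_per_round[[i]])
  }))
}

#' @method glance diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble::tibble(
    rounds = x$rounds,
    n_adopters = sum(lengths(x$adopters_per_round)),
    n_vertices = length(x$final$graph$vertices)
  )
}
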