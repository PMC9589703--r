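# Synthetic networks: small worked-example fixtures pinned by the published
# constraints, a planted-relationship generator exercising the classifier,
# and a school-friendship generator with a frequent/infrequent-drinker
# partition.

#' Worked-example fixture networks
#'
#' Small named networks used throughout the documentation and tests:
#'
#' * `fig1a`: the five-vertex network with overlapping `blue` = \{a, b, c\}
#'   (a triangle) and `red` = \{c, d, e\} (a path) — partial overlap.
#' * `fig1b`: `fig1a` after removing vertex `c` — disjoint.
#' * `fig3a`: two vertex-disjoint communities joined by the single cross edge
#'   (c, d) — disjoint and touching.
#' * `fig3b`: the identical graph with `blue` covering all vertices — red
#'   contained in blue (the pair showing a bare graph cannot distinguish
#'   relationships).
#' * `fig4`: containment with blue = \{a, b, d, e\} (edge (a, b)) inside
#'   red = \{a, b, c, d, e\} (edges (a, b), (b, c)); its intersection profile
#'   is \{2, 1, 1\}, union \{3, 1, 1\}, red-minus-blue \{1\},
#'   blue-minus-red \{\}.
#' * `fig5a`: terrorists `blue` = \{a, b\} (connected) and agents
#'   `red` = \{d, e\} joined by one edge — disjoint communities.
#' * `fig5b`: `fig5a` after removing the agents' edge (d, e).
#' * `fig7a`: directed influence network; `red` = \{d, e, f\} where `d`
#'   influences every other red vertex directly, disjoint from
#'   `blue` = \{a, b, c\}.
#'
#' `fig3a/b`, `fig4`, `fig5a/b` and `fig7a` are minimal reconstructions of
#' drawn examples, pinned by the printed vertex lists, operation sequences and
#' profile multisets rather than by pictorial layout.
#'
#' @param name Fixture name.
#' @return A `social_network`.
#' @examples
#' profile_relation(fixture_network("fig4"), "I", "blue", "red")
#' @export
fixture_network <- function(name = c("fig1a", "fig1b", "fig3a", "fig3b",
                                     "fig4", "fig5a", "fig5b", "fig7a")) {
  name <- match.arg(name)
  switch(
    name,
    fig1a = social_network(
      graph(edges = list(c("a", "b"), c("a", "c"), c("b", "c"),
                         c("c", "d"), c("d", "e"))),
      membership = list(a = "blue", b = "blue", c = c("blue", "red"),
                        d = "red", e = "red")
    ),
    fig1b = apply_operation(fixture_network("fig1a"), op_remove_vertex("c")),
    fig3a = social_network(
      graph(edges = list(c("a", "b"), c("b", "c"), c("c", "d"),
                         c("d", "e"), c("e", "f"))),
      membership = list(a = "blue", b = "blue", c = "blue",
                        d = "red", e = "red", f = "red")
    ),
    fig3b = social_network(
      graph(edges = list(c("a", "b"), c("b", "c"), c("c", "d"),
                         c("d", "e"), c("e", "f"))),
      membership = list(a = "blue", b = "blue", c = "blue",
                        d = c("blue", "red"), e = c("blue", "red"),
                        f = c("blue", "red"))
    ),
    fig4 = social_network(
      graph(edges = list(c("a", "b"), c("b", "c"))),
      membership = list(a = c("blue", "red"), b = c("blue", "red"),
                        c = "red", d = c("blue", "red"),
                        e = c("blue", "red"))
    ),
    fig5a = social_network(
      graph(edges = list(c("a", "b"), c("d", "e"))),
      membership = list(a = "blue", b = "blue", d = "red", e = "red")
    ),
    fig5b = apply_operation(fixture_network("fig5a"),
                            op_remove_edge("e", "d")),
    fig7a = social_network(
      graph(edges = list(c("a", "b"), c("b", "c"),
                         c("d", "e"), c("d", "f")),
            directed = TRUE),
      membership = list(a = "blue", b = "blue", c = "blue",
                        d = "red", e = "red", f = "red")
    )
  )
}

#' Generate a network with a planted topological relationship
#'
#' Builds a random social network whose two communities (`a` and `b`) are laid
#' out so that the requested relationship holds by construction: disjoint and
#' touch use disjoint member sets (touch forces at least one cross edge,
#' disjoint forbids them); containment nests one member set inside the other;
#' equality uses identical sets; partial overlap shares roughly half of the
#' smaller community while keeping exclusive members on both sides. Remaining
#' vertex pairs receive edges independently with probability `edge_density`.
#' Deterministic given `seed`.
#'
#' @param relationship One of `"disjoint"`, `"a-in-b"`, `"b-in-a"`,
#'   `"equal"`, `"partial-overlap"`, `"touch"`.
#' @param sizes Integer vector `c(|a|, |b|)`. Containment needs a strict size
#'   difference, equality equal sizes, partial overlap at least two vertices
#'   per side.
#' @param extra_vertices Vertices belonging to neither community.
#' @param edge_density Probability of each admissible edge.
#' @param seed Integer seed.
#' @return A `social_network` with community labels `"a"` and `"b"`.
#' @examples
#' net <- generate_with_relationship("touch", sizes = c(4, 4), seed = 1)
#' classify_relationship(net, "a", "b")
#' @export
generate_with_relationship <- function(relationship, sizes = c(5, 5),
                                       extra_vertices = 0,
                                       edge_density = 0.3, seed = 1) {
  relationship <- match.arg(relationship, RELATIONSHIP_NAMES)
  stopifnot(length(sizes) == 2, all(sizes >= 1),
            edge_density >= 0, edge_density <= 1, extra_vertices >= 0)
  na <- as.integer(sizes[1]); nb <- as.integer(sizes[2])
  layout <- switch(
    relationship,
    "disjoint" = ,
    "touch" = list(a = seq_len(na), b = na + seq_len(nb), n = na + nb),
    "equal" = {
      if (na != nb) stop("equal communities need equal sizes", call. = FALSE)
      list(a = seq_len(na), b = seq_len(na), n = na)
    },
    "a-in-b" = {
      if (na >= nb) stop("a-in-b needs |a| < |b|", call. = FALSE)
      list(a = seq_len(na), b = seq_len(nb), n = nb)
    },
    "b-in-a" = {
      if (nb >= na) stop("b-in-a needs |b| < |a|", call. = FALSE)
      list(a = seq_len(na), b = seq_len(nb), n = na)
    },
    "partial-overlap" = {
      if (min(na, nb) < 2) {
        stop("partial overlap needs at least 2 vertices per community",
             call. = FALSE)
      }
      shared <- max(1L, min(na, nb) %/% 2L)
      # a: shared block + exclusive tail; b: shared block + its own tail
      list(a = seq_len(na), b = c(seq_len(shared), na + seq_len(nb - shared)),
           n = na + nb - shared)
    }
  )
  n_total <- layout$n + extra_vertices
  vs <- sprintf("v%03d", seq_len(n_total))
  in_a <- seq_len(n_total) %in% layout$a
  in_b <- seq_len(n_total) %in% layout$b
  with_local_seed(seed, {
    pairs <- utils::combn(n_total, 2)
    cross <- (in_a[pairs[1, ]] & !in_a[pairs[2, ]] & in_b[pairs[2, ]] &
                !in_b[pairs[1, ]]) |
             (in_b[pairs[1, ]] & !in_b[pairs[2, ]] & in_a[pairs[2, ]] &
                !in_a[pairs[1, ]])
    admissible <- if (relationship == "disjoint") !cross else
      rep(TRUE, ncol(pairs))
    draw <- stats::runif(ncol(pairs)) < edge_density & admissible
    if (relationship == "touch" && !any(draw & cross)) {
      candidates <- which(cross)
      draw[candidates[sample.int(length(candidates), 1)]] <- TRUE
    }
    em <- cbind(vs[pairs[1, draw]], vs[pairs[2, draw]])
    membership <- stats::setNames(lapply(seq_len(n_total), function(i) {
      c(if (in_a[i]) "a", if (in_b[i]) "b")
    }), vs)
    social_network(graph(vertices = vs, edges = em), membership = membership,
                   labels = c("a", "b"))
  })
}

#' Generate a school-like friendship network
#'
#' Emulates a one-wave school friendship network: `n` students partitioned
#' into `frequent` and `infrequent` drinker communities, with undirected
#' friendship ties placed independently so that the expected degree is about
#' `mean_degree` and same-community ties are favoured according to
#' `homophily` (0.5 = no preference, 1 = no cross-community friendships).
#'
#' Defaults mirror a realistic adolescent friendship wave: 50 students, about
#' 40% frequent drinkers, around four friends each, and the strong
#' drinking-behaviour homophily reported for school cohorts.
#'
#' @param n Number of students.
#' @param frac_frequent Fraction belonging to the frequent-drinker community.
#' @param mean_degree Target expected number of friends per student.
#' @param homophily In `[0, 1]`: relative weight of same-community ties.
#' @param seed Integer seed.
#' @return A `social_network` with communities `frequent` and `infrequent`
#'   partitioning the vertices.
#' @export
generate_school_like <- function(n = 50, frac_frequent = 0.4,
                                 mean_degree = 4, homophily = 0.7,
                                 seed = 1) {
  stopifnot(n >= 2, frac_frequent >= 0, frac_frequent <= 1,
            homophily >= 0, homophily <= 1, mean_degree >= 0)
  vs <- sprintf("s%03d", seq_len(n))
  n_freq <- round(n * frac_frequent)
  with_local_seed(seed, {
    freq <- sample(vs, n_freq)
    membership <- stats::setNames(
      as.list(ifelse(vs %in% freq, "frequent", "infrequent")), vs
    )
    pairs <- utils::combn(n, 2)
    same <- (vs[pairs[1, ]] %in% freq) == (vs[pairs[2, ]] %in% freq)
    w <- ifelse(same, homophily, 1 - homophily)
    total_w <- sum(w)
    target_edges <- mean_degree * n / 2
    p <- if (total_w > 0) pmin(1, w * target_edges / total_w) else rep(0, length(w))
    draw <- stats::runif(ncol(pairs)) < p
    em <- cbind(vs[pairs[1, draw]], vs[pairs[2, draw]])
    social_network(graph(vertices = vs, edges = em), membership = membership,
                   labels = c("frequent", "infrequent"))
  })
}
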