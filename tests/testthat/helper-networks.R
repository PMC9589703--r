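# Shared fixtures and generators for the test suite. Every random object is
# built from an explicit seed so failures replay exactly.

eq1_network <- function() fixture_network("fig1a")

# random simple network with two (possibly overlapping) communities over at
# most `n_max` vertices; membership probabilities leave some vertices outside
# both communities
random_two_community_network <- function(seed, n_max = 12, directed = FALSE,
                                         p_edge = 0.3) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  vs <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  draw <- runif(nrow(pairs)) < p_edge
  em <- cbind(vs[pairs[draw, 1]], vs[pairs[draw, 2]])
  if (directed) {
    flip <- runif(nrow(em)) < 0.5
    em[flip, ] <- em[flip, 2:1]
  }
  membership <- stats::setNames(lapply(vs, function(v) {
    c(if (runif(1) < 0.45) "blue", if (runif(1) < 0.45) "red")
  }), vs)
  social_network(graph(vertices = vs, edges = em, directed = directed),
                 membership = membership, labels = c("blue", "red"))
}

# independent touch oracle: no shared vertex AND at least one edge of the
# network joining a member of one community to a member of the other
touch_oracle <- function(net, a, b) {
  ma <- community_members(net, a)
  mb <- community_members(net, b)
  if (length(intersect(ma, mb)) > 0) return(FALSE)
  em <- network_graph(net)$edges
  cross <- (em[, 1] %in% ma & em[, 2] %in% mb) |
           (em[, 1] %in% mb & em[, 2] %in% ma)
  any(cross)
}

# independent profile oracle: component sizes by repeated breadth-first
# traversal over an adjacency list
profile_oracle <- function(g) {
  vs <- graph_vertices(g)
  em <- g$edges
  adj <- stats::setNames(lapply(vs, function(v) {
    unique(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1]))
  }), vs)
  sizes <- integer()
  remaining <- vs
  while (length(remaining) > 0) {
    queue <- remaining[1]
    comp <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    sizes <- c(sizes, length(comp))
    remaining <- setdiff(remaining, comp)
  }
  sort(sizes, decreasing = TRUE)
}

expect_profile <- function(actual, expected) {
  expect_equal(as.integer(actual), as.integer(sort(expected,
                                                   decreasing = TRUE)))
}

# network invariant check used after edits
expect_valid_network <- function(net) {
  g <- network_graph(net)
  em <- g$edges
  expect_true(all(as.vector(em) %in% graph_vertices(g)))
  expect_true(!any(em[, 1] == em[, 2]))
  expect_equal(anyDuplicated(paste(em[, 1], em[, 2])), 0)
  if (!g$directed && nrow(em) > 0) expect_true(all(em[, 1] < em[, 2]))
  expect_identical(sort(names(network_membership(net))), graph_vertices(g))
  expect_true(all(unlist(network_membership(net)) %in%
                    community_labels(net)))
}

# ego-community intersection profile used by the coverage condition
profile_relation_ego <- function(net, v, label) {
  component_profile(graph_intersect(
    ego_community(net, v),
    graph(vertices = community_members(net, label))
  ))
}
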