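test_that("profile_relation reproduces the containment worked example", {
  f4 <- fixture_network("fig4")
  expect_profile(profile_relation(f4, "I", "blue", "red"), c(2, 1, 1))
  expect_profile(profile_relation(f4, "U", "blue", "red"), c(3, 1, 1))
  expect_profile(profile_relation(f4, "S", "blue", "red"), integer())
  expect_profile(profile_relation(f4, "S", "red", "blue"), 1)
  expect_error(profile_relation(f4, "I", "blue", "green"), "unknown")
})

test_that("I and U are symmetric, S is order-sensitive", {
  for (seed in 1:20) {
    net <- random_two_community_network(seed)
    expect_identical(profile_relation(net, "I", "blue", "red"),
                     profile_relation(net, "I", "red", "blue"))
    expect_identical(profile_relation(net, "U", "blue", "red"),
                     profile_relation(net, "U", "red", "blue"))
  }
  # a concrete asymmetric case
  net <- eq1_network()
  expect_profile(profile_relation(net, "S", "blue", "red"), 2)
  expect_profile(profile_relation(net, "S", "red", "blue"), 2)
  f4 <- fixture_network("fig4")
  expect_false(identical(profile_relation(f4, "S", "blue", "red"),
                         profile_relation(f4, "S", "red", "blue")))
})

test_that("conditions validate their arity and evaluate per definition", {
  expect_error(condition("all-singletons", "a", "b"), "takes 1")
  expect_error(condition("empty-intersection", "a"), "takes 2")
  net <- fixture_network("fig1b")
  expect_true(evaluate_condition(net, condition("empty-intersection",
                                                "blue", "red")))
  net1a <- eq1_network()
  expect_false(evaluate_condition(net1a, condition("empty-intersection",
                                                   "blue", "red")))
  expect_true(evaluate_condition(net1a, condition("nonempty-subtraction",
                                                  "blue", "red")))
  expect_true(evaluate_condition(net1a, condition("single-component-union",
                                                  "blue", "red")))
  f3a <- fixture_network("fig3a")
  expect_true(evaluate_condition(f3a, condition("touch-bound", "blue", "red")))
  # the bound alone also holds for overlapping communities (fewer union
  # components than the two communities have separately); only together with
  # empty intersection does it characterise touch
  expect_true(evaluate_condition(net1a, condition("touch-bound",
                                                  "blue", "red")))
  expect_false(evaluate_condition(fixture_network("fig1b"),
                                  condition("touch-bound", "blue", "red")))
  # single-member community is trivially all singletons
  single <- social_network(graph(vertices = "x"), membership = list(x = "a"))
  expect_true(evaluate_condition(single, condition("all-singletons", "a")))
})

test_that("empty communities evaluate per the formulas, no special cases", {
  net <- social_network(graph(edges = list(c("a", "b"))),
                        membership = list(a = "blue"),
                        labels = c("blue", "red"))
  expect_true(evaluate_condition(net, condition("empty-subtraction",
                                                "red", "blue")))
  expect_true(evaluate_condition(net, condition("empty-intersection",
                                                "blue", "red")))
  expect_true(evaluate_condition(net, condition("all-singletons", "red")))
  expect_false(evaluate_condition(net, condition("touch-bound",
                                                 "blue", "red")))
})

test_that("coverage-all counts ego/community shared vertices", {
  net <- social_network(
    graph(vertices = c("u", "w"), edges = list(c("u", "v"))),
    membership = list(v = "covering"),
    labels = "covering"
  )
  # u is adjacent to the covering member v; w is isolated and uncovered
  expect_false(evaluate_condition(net, condition("coverage-all", "covering")))
  net2 <- apply_operation(net, op_add_edge("w", "v"))
  expect_true(evaluate_condition(net2, condition("coverage-all", "covering")))
})

test_that("classification reproduces the figure relationships", {
  expect_true("partial-overlap" %in%
                classify_relationship(eq1_network(), "blue", "red"))
  expect_setequal(classify_relationship(fixture_network("fig3a"),
                                        "blue", "red"),
                  c("disjoint", "touch"))
  expect_setequal(classify_relationship(fixture_network("fig1b"),
                                        "blue", "red"),
                  "disjoint")
  expect_true("b-in-a" %in% classify_relationship(fixture_network("fig3b"),
                                                  "blue", "red"))
  f4 <- fixture_network("fig4")
  expect_true("a-in-b" %in% classify_relationship(f4, "blue", "red"))
})

test_that("identical communities classify as equal plus both containments", {
  net <- social_network(graph(edges = list(c("x", "y"))),
                        membership = list(x = c("a", "b"), y = c("a", "b")))
  expect_setequal(classify_relationship(net, "a", "b"),
                  c("equal", "a-in-b", "b-in-a"))
  expect_identical(most_specific_relationship(net, "a", "b"), "equal")
})

test_that("most specific relationship applies the documented precedence", {
  expect_identical(most_specific_relationship(c("disjoint", "touch")),
                   "touch")
  expect_identical(most_specific_relationship(c("a-in-b", "equal", "b-in-a")),
                   "equal")
  expect_identical(most_specific_relationship("partial-overlap"),
                   "partial-overlap")
  expect_identical(most_specific_relationship(character()), NA_character_)
})

test_that("equal is equivalent to two-way empty subtraction and identical subgraphs", {
  for (seed in 1:20) {
    net <- random_two_community_network(seed)
    both_empty <-
      evaluate_condition(net, condition("empty-subtraction", "blue", "red")) &&
      evaluate_condition(net, condition("empty-subtraction", "red", "blue"))
    same_subgraph <- graph_identical(community_subgraph(net, "blue"),
                                     community_subgraph(net, "red"))
    is_equal <- "equal" %in% classify_relationship(net, "blue", "red")
    expect_identical(is_equal, both_empty)
    expect_identical(is_equal, same_subgraph)
  }
})

test_that("condition sets round-trip through YAML and JSON, with shorthand", {
  dir <- withr::local_tempdir()
  cs <- condition_set(condition("all-singletons", "red"),
                      condition("empty-subtraction", "red", "blue"),
                      condition("single-component-union", "red", "blue"))
  for (f in c("target.yaml", "target.json")) {
    p <- file.path(dir, f)
    write_conditions(cs, p)
    back <- read_conditions(p)
    expect_equal(length(back), 3)
    expect_identical(vapply(back, format, character(1)),
                     vapply(cs, format, character(1)))
  }
  # relationship shorthand expands to the characterising set
  p <- file.path(dir, "short.yaml")
  yaml::write_yaml(list(relationship = "touch",
                        communities = list("blue", "red")), p)
  short <- read_conditions(p)
  expect_identical(vapply(short, function(c_) c_$kind, character(1)),
                   c("empty-intersection", "touch-bound"))
})
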