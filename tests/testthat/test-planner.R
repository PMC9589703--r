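test_that("separation planner removes exactly the shared vertices", {
  net <- eq1_network()
  p <- plan_disjoint(net, "blue", "red")
  expect_equal(length(p$ops), 1)
  expect_identical(format(p$ops[[1]]), "remove_vertex(c)")
  rep <- verify_plan(net, p)
  expect_true(rep$satisfied)
  expect_true(network_identical(rep$network, fixture_network("fig1b")))
  # the reassignment alternative keeps c but strips its red membership
  p2 <- plan_disjoint(net, "blue", "red", strategy = "reassign-membership")
  expect_equal(length(p2$ops), 1)
  expect_identical(p2$ops[[1]]$labels, "blue")
  rep2 <- verify_plan(net, p2)
  expect_true(rep2$satisfied)
  expect_identical(network_membership(rep2$network)$c, "blue")
  # already-disjoint communities need no operations
  p3 <- plan_disjoint(fixture_network("fig1b"), "blue", "red")
  expect_equal(length(p3$ops), 0)
  expect_true(verify_plan(fixture_network("fig1b"), p3)$satisfied)
})

test_that("fragmentation planner removes exactly the intra-community edges", {
  f5a <- fixture_network("fig5a")
  p <- plan_atomize(f5a, "red", other = "blue")
  expect_equal(length(p$ops), 1)
  expect_identical(p$ops[[1]]$type, "remove_edge")
  expect_setequal(c(p$ops[[1]]$from, p$ops[[1]]$to), c("d", "e"))
  rep <- verify_plan(f5a, p)
  expect_true(rep$satisfied)
  expect_true(network_identical(rep$network, fixture_network("fig5b")))
  # singleton community: nothing to do
  single <- social_network(graph(vertices = "x"), membership = list(x = "a"))
  expect_equal(length(plan_atomize(single, "a")$ops), 0)
  # triangle community: all three edges go
  tri <- social_network(graph(edges = list(c("x", "y"), c("x", "z"),
                                           c("y", "z"))),
                        membership = list(x = "a", y = "a", z = "a"))
  expect_equal(length(plan_atomize(tri, "a")$ops), 3)
  expect_true(verify_plan(tri, plan_atomize(tri, "a"))$satisfied)
})

test_that("infiltration planner emits the six worked operations", {
  f5b <- fixture_network("fig5b")
  p <- plan_infiltrate(f5b, "red", "blue")
  got <- vapply(p$ops, format, character(1))
  expect_identical(got, c(
    "set_membership(d, {blue, red})", "set_membership(e, {blue, red})",
    "add_edge(d, a)", "add_edge(d, b)", "add_edge(e, a)", "add_edge(e, b)"
  ))
  rep <- verify_plan(f5b, p)
  expect_true(rep$satisfied)
  expect_true("a-in-b" %in% rep$summary$classification)
  # dropping both of e's new edges isolates e and breaks the
  # single-union-component condition while the other two conditions survive
  p_cut <- p; p_cut$ops <- p_cut$ops[1:4]
  rep_cut <- verify_plan(f5b, p_cut)
  expect_false(rep_cut$satisfied)
  bad <- rep_cut$per_condition
  expect_false(bad$satisfied[bad$kind == "single-component-union"])
  expect_true(all(bad$satisfied[bad$kind != "single-component-union"]))
})

test_that("infiltration snapshots memberships and skips present edges", {
  # one agent, three hosts, one pre-existing cross edge
  net <- social_network(graph(vertices = c("x", "p", "q", "r"),
                              edges = list(c("p", "x"))),
                        membership = list(x = "a", p = "b", q = "b", r = "b"))
  p <- plan_infiltrate(net, "a", "b")
  types <- vapply(p$ops, function(o) o$type, character(1))
  expect_equal(sum(types == "set_membership"), 1)
  expect_equal(sum(types == "add_edge"), 2)  # x-p already present
  expect_true(verify_plan(net, p)$satisfied)
  # empty infiltrating community: empty plan
  net2 <- social_network(graph(vertices = c("p", "q")),
                         membership = list(p = "b", q = "b"),
                         labels = c("a", "b"))
  expect_equal(length(plan_infiltrate(net2, "a", "b")$ops), 0)
})

test_that("influence-containment seeds a dominating set and defers to diffusion", {
  f7 <- fixture_network("fig7a")
  p <- plan_influence_containment(f7, "red", "blue")
  expect_identical(vapply(p$ops, format, character(1)),
                   "set_membership(d, {blue, red})")
  expect_identical(p$diffusion, list(within = "red", adopt = "blue"))
  rep <- verify_plan(f7, p)
  expect_true(rep$satisfied)
  expect_true(all(vapply(community_members(rep$network, "red"),
                         function(v) "blue" %in%
                           network_membership(rep$network)[[v]],
                         logical(1))))
  # before diffusion the subtraction is non-empty: membership change alone
  # does not contain the community
  seeded <- apply_operations(f7, p$ops)
  expect_false(evaluate_condition(seeded, condition("empty-subtraction",
                                                    "red", "blue")))
  # singleton community seeds itself
  s <- social_network(graph(vertices = "v", directed = TRUE),
                      membership = list(v = "red"),
                      labels = c("blue", "red"))
  ps <- plan_influence_containment(s, "red", "blue")
  expect_equal(length(ps$ops), 1)
  # two-hub star: both hubs needed
  twostar <- social_network(
    graph(edges = list(c("h1", "x1"), c("h1", "x2"), c("h2", "y1"),
                       c("h2", "y2")), directed = TRUE),
    membership = list(h1 = "red", h2 = "red", x1 = "red", x2 = "red",
                      y1 = "red", y2 = "red"),
    labels = c("blue", "red")
  )
  pt <- plan_influence_containment(twostar, "red", "blue")
  expect_setequal(vapply(pt$ops, function(o) o$vertex, character(1)),
                  c("h1", "h2"))
  expect_true(verify_plan(twostar, pt)$satisfied)
  # undirected networks are rejected
  expect_error(plan_influence_containment(eq1_network(), "red", "blue"),
               "directed")
})

test_that("coverage planner adds one edge per uncovered vertex", {
  # three isolated frequent vertices, single covering member
  net <- social_network(
    graph(vertices = c("f1", "f2", "f3", "b1")),
    membership = list(f1 = "freq", f2 = "freq", f3 = "freq", b1 = "inf")
  )
  p <- plan_coverage(net, "inf", seed = 5)
  expect_equal(length(p$ops), 3)
  expect_true(all(vapply(p$ops, function(o) o$to, character(1)) == "b1" |
                    vapply(p$ops, function(o) o$from, character(1)) == "b1"))
  expect_true(verify_plan(net, p)$satisfied)
  # already-covered network yields the empty plan
  done <- verify_plan(net, p)$network
  expect_equal(length(plan_coverage(done, "inf", seed = 1)$ops), 0)
  # empty covering community is an error
  none <- social_network(graph(vertices = "x"), membership = list(),
                         labels = "inf")
  expect_error(plan_coverage(none, "inf"), "no members")
})

test_that("coverage plan length is seed-independent, partners are not", {
  net <- generate_school_like(n = 40, seed = 11)
  lens <- vapply(1:5, function(s) {
    length(plan_coverage(net, "infrequent", seed = s)$ops)
  }, integer(1))
  expect_equal(length(unique(lens)), 1)
  expect_true(verify_plan(net, plan_coverage(net, "infrequent",
                                             seed = 2))$satisfied)
  # same seed, same plan
  p1 <- plan_coverage(net, "infrequent", seed = 9)
  p2 <- plan_coverage(net, "infrequent", seed = 9)
  expect_identical(vapply(p1$ops, format, character(1)),
                   vapply(p2$ops, format, character(1)))
})

test_that("verification is pure and reports application failures", {
  net <- eq1_network()
  p <- plan_disjoint(net, "blue", "red")
  invisible(verify_plan(net, p))
  expect_true(network_identical(net, eq1_network()))
  # a plan whose operation cannot apply reports the failing index
  broken <- p; broken$ops <- list(op_remove_vertex("zz"))
  rep <- verify_plan(net, broken)
  expect_false(rep$satisfied)
  expect_equal(rep$failure$index, 1)
  expect_match(rep$failure$message, "absent vertex")
})

test_that("infeasible plans fail loudly, naming the blocked variant", {
  net <- eq1_network()
  no_removals <- feasibility_policy(policy_rule("E+"), policy_rule("E-"))
  err <- expect_error(plan_disjoint(net, "blue", "red", policy = no_removals),
                      class = "commtopo_infeasible_plan")
  expect_match(conditionMessage(err), "remove_vertex")
  expect_error(plan_atomize(fixture_network("fig5a"), "red",
                            policy = feasibility_policy()),
               class = "commtopo_infeasible_plan")
})

test_that("the dispatcher honours policy, plan length and declaration order", {
  net <- eq1_network()
  # both separation strategies feasible and tied at one op: declaration order
  # selects vertex removal
  p <- plan_intervention(net, "disjoint", "blue", "red")
  expect_identical(p$strategy, "disjoint/remove-vertex")
  # only membership reassignment allowed: fall through to it
  cd_only <- feasibility_policy(policy_rule("CD"))
  p2 <- plan_intervention(net, "disjoint", "blue", "red", policy = cd_only)
  expect_identical(p2$strategy, "disjoint/reassign-membership")
  # target already satisfied: empty plan
  p3 <- plan_intervention(fixture_network("fig1b"), "disjoint", "blue", "red")
  expect_equal(length(p3$ops), 0)
  # a condition-set target maps onto a registered strategy
  cs <- condition_set(condition("empty-intersection", "blue", "red"))
  expect_identical(plan_intervention(net, cs, "blue", "red")$strategy,
                   "disjoint/remove-vertex")
  # nothing feasible: error lists what was tried
  err <- expect_error(
    plan_intervention(net, "disjoint", "blue", "red",
                      policy = feasibility_policy()),
    class = "commtopo_infeasible_plan"
  )
  expect_match(conditionMessage(err), "tried")
})

test_that("plans round-trip through JSON", {
  dir <- withr::local_tempdir()
  plans <- list(
    plan_infiltrate(fixture_network("fig5b"), "red", "blue"),
    plan_influence_containment(fixture_network("fig7a"), "red", "blue"),
    plan_coverage(generate_school_like(n = 20, seed = 2), "infrequent",
                  seed = 4)
  )
  for (p in plans) {
    f <- file.path(dir, "plan.json")
    write_plan(p, f)
    back <- read_plan(f)
    expect_identical(vapply(back$ops, format, character(1)),
                     vapply(p$ops, format, character(1)))
    expect_identical(vapply(back$target, format, character(1)),
                     vapply(p$target, format, character(1)))
    expect_identical(back$strategy, p$strategy)
    expect_identical(back$diffusion, p$diffusion)
  }
})

test_that("plan tidiers expose operations and headline summaries", {
  p <- plan_infiltrate(fixture_network("fig5b"), "red", "blue")
  td <- tidy(p)
  expect_equal(nrow(td), 6)
  expect_identical(td$type[1:2], rep("set_membership", 2))
  gl <- glance(p)
  expect_identical(gl$strategy, "infiltrate")
  expect_equal(gl$n_ops, 6)
  expect_false(gl$needs_diffusion)
  rep <- verify_plan(fixture_network("fig5b"), p)
  expect_true(all(tidy(rep)$satisfied))
  expect_identical(glance(rep)$relationship, "a-in-b")
})
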