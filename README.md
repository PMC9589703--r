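# commtopo

Qualitative topological relationships between social-network communities, and
interventions planned in terms of them.

Practitioners who intervene on social networks — epidemiologists reducing
network support for risky behaviour, public-health teams seeding influence,
security analysts separating or infiltrating groups — usually reason at the
level of *relationships between communities*: these two groups must become
**disjoint**, that one must end up **contained** in this one, every
individual must **touch** the protective community. `commtopo` makes that
level of reasoning computable for R users working with community-labelled
graphs: it classifies the relationship between two communities, lets an
intervention be *defined* as a desired relationship, *compiles* it into a
sequence of concrete, policy-feasible network edits, and *verifies* the
result.

## The model

A social network is a simple graph $G=(V,E)$ plus community types $L$ and a
crisp membership map $V \to 2^L$ (vertices may belong to zero or several
communities); a community is the vertex-induced subgraph of its members. The
relationship between communities $A$ and $B$ is characterised through the
component-profile map

$$T(g) = \{\, |V'| : (V',E') \text{ a connected component of } g \,\}$$

(a multiset of component sizes) applied to the intersection, union and
subtractions of the two community subgraphs. Each named relationship is a
conjunction of conditions on these profiles — e.g. disjoint is
$T \circ I(A,B) = \{\}$, containment of $A$ in $B$ is
$T \circ S(A,B) = \{\}$, and touch is disjointness plus
$|T \circ U(A,B)| < |T(A)| + |T(B)|$. An intervention targets such a
condition set; five planners compile targets into edit sequences
(vertex removal, edge addition/removal, membership reassignment) restricted
by a declarative feasibility policy, with planner-specific guarantees that
`verify_plan()` machine-checks after application — including assimilative
influence diffusion where the plan relies on it.

## Worked example

The five-vertex network with overlapping communities — `blue` a triangle
{a, b, c}, `red` a path {c, d, e} sharing vertex `c`:

```r
library(commtopo)

net <- fixture_network("fig1a")
net
#> <social_network: 5 vertices, 5 undirected edges, 2 communities>
#>   blue: {a, b, c}
#>   red: {c, d, e}

classify_relationship(net, "blue", "red")
#> [1] "partial-overlap"
```

The shared vertex makes the pair partially overlapping. Define the
intervention "make them disjoint" and compile it:

```r
plan <- plan_intervention(net, "disjoint", "blue", "red")
plan
#> <intervention plan: strategy 'disjoint/remove-vertex', 1 operation(s)>
#>   remove_vertex(c)
#> target:
#>   empty-intersection(blue, red)
```

One operation suffices: removing the shared individual (in an application
domain, e.g. detaining them or confiscating their device). Verification
applies the plan to a copy and evaluates the target conditions:

```r
report <- verify_plan(net, plan)
report
#> <verification report: SATISFIED>
#>   [ok] empty-intersection(blue, red)
#> resulting relationship: disjoint

glance(report)
#> # A tibble: 1 × 6
#>   satisfied n_conditions n_satisfied n_vertices n_edges relationship
#>   <lgl>            <int>       <int>      <int>   <int> <chr>
#> 1 TRUE                 1           1          4       2 disjoint
```

The removal leaves four vertices and two edges, and the communities are now
disjoint. Under a policy that only permits membership reassignment, the same
target compiles to the alternative implementation
(`set_membership(c, {blue})`) instead — see `plan_intervention()` and
`feasibility_policy()`.

Other planners follow the same pattern: `plan_atomize()` fragments a
community into singletons, `plan_infiltrate()` embeds one community in
another, `plan_influence_containment()` seeds influential members and lets
`propagate_influence()` spread the membership along directed influence
edges, and `plan_coverage()` guarantees every individual a neighbour in a
covering community (e.g. an infrequent-drinker friend for every student).
Fixtures (`fixture_network()`) and generators
(`generate_with_relationship()`, `generate_school_like()`) provide ready
test networks, and `read_network()` / `write_network()`, GraphML and JSON
round trips connect to external data. A thin command-line front end lives at
`inst/cli/commtopo.R`.

## Vignette

`vignettes/community-topology.Rmd` documents the relationship calculus, the
union semantics at community level, each planner's guarantee and its
assumptions, the diffusion model, and what the synthetic generators do and do
not emulate.
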