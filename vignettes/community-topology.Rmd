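---
title: "Topological relationships between communities and planned interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological relationships between communities and planned interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commtopo)
```

## The model

A social network here is a simple graph $G=(V,E)$ — vertices are individuals,
edges are ties such as friendship, information flow or directed social
influence — together with a set of community types $L$ and a crisp membership
map assigning each vertex a subset of $L$. A vertex may belong to zero, one or
several communities; a community is realised as the vertex-induced subgraph of
its members. `commtopo` deliberately derives community subgraphs on demand
instead of storing them, so no sequence of edits can leave a community's edge
set inconsistent with the graph.

Two communities $A$ and $B$ stand in a qualitative *topological relationship*
— disjoint, contained, equal, partially overlapping, touching. A bare graph
cannot distinguish these (the `fig3a`/`fig3b` fixtures share one graph yet one
pair is disjoint and the other nested), so the relationship is characterised
through three graph-valued binary relations — intersection $I$, union $U$ and
subtraction $S$ of the two community subgraphs — composed with the
component-profile map

$$T(g) = \{\, |V'| : (V', E') \text{ a connected component of } g \,\},$$

the multiset of connected-component sizes. A profile is stored canonically as
a non-increasing integer sequence; equality is multiset equality, and its
elements always sum to the graph's vertex count. Directed graphs are profiled
under weak connectivity: for the containment reasoning an influence tie is a
connection regardless of direction.

Each named relationship is equivalent to a conjunction of conditions on these
profiles:

| relationship      | necessary and sufficient conditions |
|-------------------|-------------------------------------|
| disjoint          | $T \circ I(A,B) = \{\}$ |
| $A$ in $B$        | $T \circ S(A,B) = \{\}$ |
| $B$ in $A$        | $T \circ S(B,A) = \{\}$ |
| equal             | both subtractions empty |
| partial overlap   | intersection and both subtractions non-empty |
| touch             | $T \circ I(A,B) = \{\}$ and $|T \circ U(A,B)| < |T(A)| + |T(B)|$ |

The names are not mutually exclusive — touch implies disjoint, equality
implies both containments — so `classify_relationship()` returns every
satisfied name and `most_specific_relationship()` applies the precedence
equal > containment > touch > disjoint / partial overlap.

### The union at community level

One design point deserves emphasis. On bare graphs, `graph_union()` is the
literal union of vertex and edge sets. Induced community subgraphs, however,
can never contain an edge joining a member of $A$ to a member of $B$ when the
two member sets are disjoint — such an edge is induced by neither community.
Under a literal set-union the touch bound
$|T \circ U| < |T(A)| + |T(B)|$ could therefore never hold: the union would
always have exactly as many components as the two communities combined. All
worked union values are equally consistent with reading $U(A,B)$ as the
induced subgraph on the union of the member sets, and only that reading makes
the touch characterisation correct, because it retains the cross-community
edges that the bound counts. `profile_relation(net, "U", a, b)` — and hence
every condition — uses the induced reading; the two coincide whenever no
cross-community edge exists. Intersection and subtraction are unaffected:
for induced subgraphs the set forms already equal the induced forms.

A related caveat: two printed worked values in the source material for this
model (the intersection of the overlapping five-vertex pair, and one
subtraction on its disjoint counterpart) contradict the formal definitions by
a single vertex set; the implementation follows the definitions, under which
all other printed values reproduce exactly.

## Interventions

An intervention is *defined* as a target condition set and *implemented* as a
sequence of atomic edits: `remove_vertex` (incident edges go too),
`add_edge`, `remove_edge`, and `set_membership`, which replaces a vertex's
label set. Edits are strict — adding a present edge or removing an absent one
is an error, so every applied operation is auditable; planners, not the edit
layer, decide to skip redundant edits. What an edit may be used at all is a
*feasibility policy*: an ordered rule list gating each operation type on
membership predicates over the operation's own vertices (e.g. edge removal
only between undercover agents). Every statement of feasibility in the
motivating applications is expressible this way; arbitrary predicate guards
are accepted programmatically but do not serialise.

Five planners compile targets into operation sequences, and
`verify_plan()` re-applies a plan to a copy and evaluates every target
condition, so each plan's guarantee is machine-checked rather than assumed:

* **Separation** (`plan_disjoint`): removes every shared vertex, or — the
  alternative implementation — strips one community's label from each shared
  vertex. Plan length equals the size of the intersection.
* **Fragmentation** (`plan_atomize`): removes every intra-community edge,
  leaving all-singleton components. Plan length equals the intra-community
  edge count.
* **Infiltration** (`plan_infiltrate`): each member of $A$ additionally joins
  $B$, then an edge is added between every non-adjacent (original) $A$–$B$
  pair. Memberships are snapshotted before editing: without the snapshot,
  after the reassignments $A \subseteq B$ and the pair loop would add edges
  inside $A$, contradicting both the worked six-operation sequence and the
  all-singletons clause of the target.
* **Influence containment** (`plan_influence_containment`): picks "highly
  influential" members of $A$ — operationalised as a greedy minimum
  in-dominating set, the weakest structural reading under which the
  containment guarantee is provable (every non-seed member receives a direct
  influence edge from a seed) — and reassigns only those; assimilative
  influence does the rest. Alternative seed selectors can be composed by
  emitting the `set_membership` operations directly.
* **Coverage** (`plan_coverage`): for every vertex whose *ego community* (the
  vertex plus its neighbours, taken with an empty edge set, so that profile
  cardinality counts shared vertices) misses the covering community, one edge
  to a uniformly chosen covering member is added. The loop runs over all
  vertices rather than only the non-covering community; the two coincide
  whenever the two communities partition the vertex set, and the all-vertex
  form matches the universally quantified target condition.

`plan_intervention()` dispatches a named target over the registered
strategies in declared order, keeping every plan whose operation variants the
policy permits and returning the shortest (ties to declaration order). The
planners assume the network is static while a plan is computed and applied;
re-planning after external change is the caller's responsibility.

### Assimilative influence

Influence containment only reaches its target after influence propagates.
`propagate_influence()` runs synchronous rounds: every member of the confined
community with an in-neighbour (in that community) already carrying the
adopted labels gains them. The dynamics are the simplest monotone fixpoint
consistent with the provable one-round case — the motivating model specifies
no dynamics beyond adoption "through influence", so this choice is an
explicit assumption: labels are only added, propagation stays inside the
community (no spillover), and termination within $|V|$ rounds follows from
monotonicity. Whether influence should instead require multiple exposures or
flow through non-adopting intermediaries is deliberately out of scope.

## Randomness, determinism and numerical choices

Vertex identifiers are opaque strings and every deterministic operation
iterates in lexicographic order, so plans and edits are reproducible
bit-for-bit. All stochastic steps (the generators, coverage partner choice)
flow through one explicit integer seed, restored-on-exit so library calls
never perturb the caller's RNG state; the seed used is recorded in the plan.
Greedy tie-breaks (dominating-set seed choice) take the lexicographically
first maximiser. Degenerate inputs follow the formulas with no special cases:
an empty community is vacuously all-singletons and vacuously contained in
anything, the empty graph has the empty profile, and an empty feasibility
policy permits nothing.

## What the generators emulate — and what they do not

`generate_with_relationship()` plants member sets so a requested relationship
holds *by construction* (disjoint additionally forbids cross-community edges
so the plant is not also touching; touch forces at least one), then sprinkles
edges independently at a requested density. It exercises the classifier and
the planners' preconditions across thousands of seeds, but real communities
are not Erdős–Rényi: no degree heterogeneity, no triadic closure.

`generate_school_like()` emulates one wave of a school friendship network:
`n = 50` students, a `frac_frequent = 0.4` frequent-drinker share,
`mean_degree = 4` friendships per student, and homophily 0.7 (same-community
pairs get a 0.7 : 0.3 weight ratio, rescaled so the expected degree hits the
target; homophily 1 forbids cross-community friendship entirely). These
defaults were fixed once as plausible for an adolescent cohort — a minority
of frequent drinkers, a handful of friends each, strong behavioural homophily
— and the tests inherit them rather than tune them. Passing tests on these
populations show the planner guarantees hold under the stated preconditions;
they do not show anything about nomination asymmetry, longitudinal change or
the degree distribution of any particular real cohort. The
`read_school_excerpt()` loader ingests the published adjacency/attribute text
format of the real 50-student excerpt for users who have downloaded it; no
test or example depends on that file.

Property suites run the five planner guarantees on 1000 seeded networks per
planner (up to 30 vertices, preconditions planted), the touch
characterisation against a brute-force oracle on 1000 networks of up to 12
vertices, and the generator–classifier round trip for all six relationships
across 100 seeds each — sizes chosen so the whole population is exercised in
a couple of minutes while staying large enough that a symmetry or boundary
defect would surface.

## Worked example

```{r example}
net <- fixture_network("fig1a")
classify_relationship(net, "blue", "red")

plan <- plan_intervention(net, "disjoint", "blue", "red")
tidy(plan)

report <- verify_plan(net, plan)
glance(report)
```

Restricting the policy to membership reassignment switches the
implementation without changing the target:

```{r policy}
cd_only <- feasibility_policy(policy_rule("CD"))
plan_intervention(net, "disjoint", "blue", "red", policy = cd_only)
```

## Known limitations

* Plans are feasible and correct, not optimal: infiltration adds every
  missing cross pair even where a spanning subset would connect the union,
  and no cost or success-probability model is attached to operations.
* Crisp membership only; fuzzy or weighted community membership is out of
  scope, as are weighted and temporal edges.
* Community *detection* is assumed done: the model starts from given
  memberships.
* The diffusion dynamics are an assumption (see above), chosen for
  determinism and provability, not fitted to behavioural data.
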