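---
title: "Mining semantic networks for drug-target interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining semantic networks for drug-target interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dresmin)
```

## The graph model

The target network *G* is a typed, directed, attributed multigraph: parallel
edges and self-loops are allowed, every vertex carries a concept class
(`Compound`, `Target`, `Protein`, `Disease`, ...) and every edge a relation
type (`binds_to`, `similar_to`, ...).  Attributes are carried as opaque
textual payload; the algorithms only read types and topology.  Identifiers
and type names are case-sensitive and compared byte-wise.  Degree counts
edge multiplicity, and a self-loop contributes one to the in-degree and one
to the out-degree; this convention matters because the candidate rule
$\deg_G(v) \ge \deg_Q(v)$ must never under-count.

A query *Q* is a small connected typed digraph over abstract roles,
optionally annotated with an inference triple (drug role, target role,
inferred edge type).  An embedding of *Q* in *G* is an injective assignment
of roles to vertices and of query edges to distinct target edges that
preserves direction, plus two additional requirements described next.

## The matching contract

**Closed world.**  When a query encodes a repositioning pattern, the absence
of an edge is evidence of no relationship.  A complete assignment is
therefore accepted only if every target edge between mapped vertices
(including self-loops on mapped vertices) is the image of some query edge —
an *induced* match.  We implement the rule in this textual form; the
degree-equivalence formulation sometimes quoted alongside it (requiring
$\deg_G(v) = \deg_Q(m)$ for mapped pairs) would contradict the candidate
rule $\deg_G \ge \deg_Q$, since a mapped vertex may have any number of edges
to *unmapped* vertices.  For users who do want the literal degree-equality
semantics, `search_config(strict_degree = TRUE)` adds that check on top.

**Semantic thresholding.**  Each element of a mapping (every role/vertex
pair and every query-edge/target-edge pair) is scored by the semantic
distance calculator, a pair of square symmetric matrices over vertex and
edge types with entries in $[-1, 1]$, diagonal 1.  The canonical matrices
are identities (1 identical, 0 unrelated) and `identity_sdc()` builds them,
but entries are graded reals, not just $\{-1, 0, 1\}$: non-identical types
with similar semantics can legitimately contribute to a match, and users
encode hierarchy-derived similarity directly in the matrices.  A type pair
absent from a matrix scores 0 ("unrelated") rather than raising an error,
so a network with extra types needs no matrix edits.  The semantic score of
a mapping is the mean over its $n = |V(Q)| + |E(Q)|$ elements.  Two
threshold modes exist: *per element* (every element $\ge ST$) and
*cumulative* (the mean $\ge ST$).  All comparisons use $\ge$ with a
$10^{-12}$ floating-point guard, so a mapping exactly at the threshold is
accepted.

## The search

The matcher is a VF-style exhaustive depth-first backtracking search.

* **Anchor and initial candidates.**  The search starts at the query role
  of the configured anchor type (default `Compound`, reflecting that every
  useful mapping must contain a compound) with maximum degree, ties broken
  by smallest role id; if no role has the anchor type the globally
  max-degree role is used with a warning.  Its candidates are the target
  vertices passing the semantic test whose total degree is at least the
  anchor's query degree.
* **Recursion order.**  The next role is always adjacent to the already
  mapped set, most constrained (highest degree) first, ties by role id.
  Candidates for it are drawn from neighbours of mapped images, never the
  whole graph.
* **Incremental pruning.**  On each tentative assignment the engine checks
  the semantic test, the degree rule, self-loop counts, and — against every
  previously mapped role — that the number of target edges in each
  direction equals the number of query edges (the closed-world rule applied
  pairwise, which also rejects any edge between images of non-adjacent
  roles).
* **Leaf finalisation.**  A complete assignment is re-verified over all
  role pairs, and the edge bijection is enumerated group by group (parallel
  query edges between the same role pair must map to distinct parallel
  target edges; each bijection is a distinct mapping).  The semantic score
  is computed and the threshold applied.

In cumulative mode, branches are cut with the admissible bound
$\text{partial sum} + (\text{elements remaining}) \ge ST \cdot n$: only
provably hopeless branches are pruned.  The initial candidate set uses the
same bound (with one scored element) rather than a hard score cut-off, so
no mapping whose mean could still reach the threshold is ever excluded.

Mapping identity is the vertex assignment together with the edge
assignment; automorphic re-embeddings of *Q* onto the same target elements
count as distinct mappings.  This raw-count semantics is what makes the
spiked-recovery arithmetic exact for rigid queries.  An orbit-deduplication
flag (`dedup_orbits`) collapses them when desired, and `max_mappings` caps
the result set.

`brute_force_search()` is the package's independent oracle: it enumerates
injective assignments in plain sorted-role order with only the definitional
edge-existence requirement as pruning and applies the full contract at each
leaf, sharing none of the anchor/ordering/closed-world machinery.  The test
suite asserts set equality between the two on hundreds of seeded instances,
including multigraphs with self-loops, parallel edges and graded matrices.

## Semantic graph pruning

Before a search, vertices whose type is semantically distant from every
query vertex type can be removed, together with their edges and any vertex
left isolated.  A target type survives if its *best* score against the
query's vertex types reaches the threshold; the maximum is the right
aggregation because a type close to any single query type may participate
in a mapping.  In per-element mode pruning is loss-free (no vertex of a
surviving mapping can be removed) and defaults on.  In cumulative mode a
below-threshold element could be absorbed by a high-scoring mapping, so
pruning could change results; it therefore defaults off there.

## Query splitting

Searching large queries directly is expensive; queries with four or more
roles are recursively split into parts with at most three roles.

One round works on the undirected view: the most connected role becomes the
overlap node (*ON*; ties by minimum eccentricity, then role id — degree
ties are common in small queries, so a structural tie-break is needed);
among the remaining roles, the pair at maximum *pairwise* distance
$(v_1, v_2)$ is chosen (ties by smallest sorted id pair).  We read "most
distant" as pairwise distance between the two vertices rather than distance
from the ON because the canonical split of a path picks its two endpoints.
Part $D_1$ receives the roles on the shortest path $v_1 \to ON$ and $D_2$
those on $v_2 \to ON$ (among equal-length paths the lexicographically
smallest role-id sequence, for determinism); every remaining role joins the
part holding more of its already-allocated neighbours (ties: the smaller
part, then $D_1$).  Each edge is allocated to the part containing both its
endpoints ($D_1$ first) or to the residual set.

Two implementation notes.  First, when the two chosen paths overlap beyond
the ON, a strictly partitioned edge set can leave a part disconnected; the
part query graphs therefore carry their *induced* edge sets for searching,
while `split_recursive()`'s `edge_allocation` records the exact partition.
Second, a degenerate allocation that fails to shrink the query falls back
to a balanced partition of the BFS subtrees hanging off the ON; this
safeguard does not affect correctness because every joined mapping is
re-verified against the full query.

`split_search()` searches the smaller part first, seeded at the ON whose
candidates keep the *full-query* degree of that role; the ON images that
yielded embeddings seed the second part's search.  Partial mappings cannot
be checked for the closed world (edges to roles outside the part are
invisible), so parts run with count-compatibility ($\ge$) only.  Joined
assignments must agree on all shared roles, be injective elsewhere, and
realise the residual edges; each joined full assignment is then finalised
exactly as in the plain search — closed world over all pairs, edge
bijection, semantic score recomputed from scratch on the full mapping (part
scores are never combined).  This re-finalisation is what guarantees
`split_search()` returns exactly the plain-search result, which the test
suite asserts on seeded instances up to $|V(G)| = 10^4$ and
$|V(Q)| = 4..9$.

## Query derivation and deduplication

Given known drug–target pairs from a newer knowledge release, the *relevant*
ones are those whose drug and target both exist in the network but are not
yet linked by an interaction edge.  For each relevant pair the shortest
semantic path is extracted on the undirected view (unit edge weights; the
lexicographically smallest vertex-id sequence among minimum-hop paths, and
the smallest-id edge between consecutive vertices — a single deterministic
path per pair).  The path becomes a *type-level* query: roles carry the path
vertex types, identities are not pinned, and the inference annotation joins
the first and last roles with the interaction edge type.  Paths are
computed on the graph as given; the pair's own direct edge cannot occur
because relevant pairs have none.

Derived queries are grouped by exact typed-digraph isomorphism (topology,
types, direction, inference annotation), computed by exhaustive
type-partitioned permutation — feasible at the ≤ 9-role sizes kept here
(larger queries are discarded with a warning).  Exact isomorphism, rather
than a type-multiset comparison, is used because distinct query classes
sharing a type multiset but differing in topology match different
subgraphs.

## Ranking

A query's score is $R_q = |Q(I) \cap \text{known}| / |Q(I)|$ where $Q(I)$
is its set of *unique* inferred pairs — the denominator deduplicates
because the intersection in the numerator is a set operation; a query with
no inferences scores 0 by convention.  Each inferred interaction accumulates
$R_i = \sum R_q$ over the queries whose unique inference sets contain it
(one query counts once however many of its mappings infer the pair), so
$R_i$ is bounded by the sum of all query scores.  Ranking is by descending
$R_i$; the tie-break (supporter count, then drug id, then target id) is a
deterministic artifact choice.  Interactions already present as interaction
edges in the network are filtered from ranked output — the closed world
already prevents them; the filter is belt-and-braces.

## Synthetic data: what it emulates, and what it does not

`random_graph()` realises a spec exactly: fixed per-type vertex counts and,
for each metagraph triple, a fixed number of edges with uniformly sampled
endpoints (self-loops resampled, parallels allowed).  Exact per-triple
counts maintain per-type average in/out degrees by construction, which is
the profile the evaluation design requires; degree *sequences* are
binomial-like, so heavy-tailed hubs of real integrated networks are not
reproduced.  `drug_network_spec()` fixes the package's default study
conditions: four core concept classes (Compound 35%, Target 20%, Protein
30%, Disease 15%) connected by eight triples (compound similarity, binding,
indications, target similarity, disease involvement, target–protein
identity, protein sequence similarity, a disease hierarchy) at an average
total degree near 3.4.  Relative class connectivity follows an integrated
drug-discovery network; absolute densities are scaled to desk size — the
extreme hub connectivity of real protein classes (average degrees an order
of magnitude higher) is deliberately not reproduced, so passing tests say
nothing about wall-clock behaviour on such hubs.

Planted instances are built from fresh vertices with exactly the query's
edges and no edges to the rest of the graph.  Isolation is essential for
the $+k$ arithmetic: a planted copy wired into the bulk could both create
mixed mappings and violate the closed world.  With a *rigid* query (no
non-trivial type-respecting automorphism — guaranteed when all vertex types
are distinct, checkable with `query_is_rigid()`), each copy contributes
exactly one mapping, so spiking a graph with 100 copies must raise the
mapping count by exactly 100; the acceptance script recomputes this at
$|V(G)| = 10^4$.

`random_query()` grows a random spanning tree plus extra edges.  With a
metagraph supplied, growth is type-consistent (each new role attaches via an
allowed triple), which is the meaningful regime for non-trivial match
counts; without one, types are i.i.d. and most random queries are
unrealisable in a given graph — useful for exercising fast rejection, not
for recovery studies.

The held-out ranking study in the test suite generates compound families
(three mutually similar binders and one structurally similar non-binding
decoy per family, two mutually similar targets, binding probability 0.9 for
binders and 0.1 for the decoy), holds out 20% of binder edges, derives
queries from the remaining graph and checks that held-out pairs achieve a
better median rank than an equal-sized random sample of other inferred
pairs.  The decoy design matters: genuine interactions are corroborated
along several metapaths (compound similarity *and* target similarity),
while decoy inferences rest on similarity alone — which is exactly the
signal the cumulative $R_i$ score is meant to exploit.  An earlier design
with a similarity ring made decoys as well-connected as binders and the
separation vanished; the study keeps decoys peripheral, which we consider
the realistic reading of "structurally similar non-binder".

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `st` | 0.8 | semantic threshold in \[0, 1\]; 0.8 accepts near-identical semantics |
| `mode` | `per_element` | threshold each element, or the mean (`cumulative`) |
| `anchor_type` | `Compound` | type of the initial candidate set |
| `prune` | on (per-element), off (cumulative) | semantic graph pruning |
| `split` | auto | split-and-join for queries with ≥ 4 roles |
| `max_mappings` | unlimited | cap on returned mappings |
| `dedup_orbits` | off | collapse automorphic re-embeddings |
| `strict_degree` | off | literal degree-equality closed-world variant |

## Numerical and degenerate-input choices

Threshold and score comparisons carry a $10^{-12}$ guard so that exact
boundary cases (e.g. a mean of exactly $ST$) are accepted regardless of
floating-point representation.  SDC matrices are validated on load: entries
in $[-1, 1]$, unit diagonal, symmetry (tolerance $10^{-12}$).  Empty target
graphs, queries larger than the graph, and empty candidate sets yield empty
results rather than errors; disconnected queries are rejected at
construction.  All tie-breaks (anchor, recursion order, ON selection,
distant pair, path choice, ranking) are deterministic and documented above,
so every run is reproducible from its inputs and seed.

## Problem sizes used by the checks

The test suite verifies oracle equivalence on 25 seeded 45-vertex graphs
with 3–6-role queries in both threshold modes; split/plain equivalence
additionally on a 10,000-vertex graph with 4–9-role queries; prune safety
across the oracle suite; planted recovery (+100) at 10,000 vertices; the
split leaf bound over 50 random 6-role queries; and the held-out study on a
180-vertex family graph.  These sizes were chosen as the smallest at which
each property is informative.  With pruning, splitting and the semantic
calculator enabled, search cost grows close to linearly with the target
graph over this range, in contrast to the steep growth of a purely
topological search; the package makes no asymptotic claim beyond it.

## Known limitations

* Matching is topologically exact; no edit-distance or inexact variant.
* Pruning is vertex-type-driven only; edge types do not prune the graph.
* Derivation takes a single deterministic shortest path per pair; unions of
  all shortest paths interact badly with the closed-world rule (shared
  neighbours of the union introduce extra induced edges) and are not used.
* Matrices must be supplied or identity; no ontology-derived similarity is
  computed.
* Scores ignore attributes and provenance; only types and topology count.
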