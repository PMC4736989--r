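# dresmin

Exhaustive semantic subgraph mining of integrated drug–target networks.

## The problem

Integrated biomedical networks describe drugs, protein targets, diseases and
the relations between them as a typed, directed, attributed multigraph:
vertices carry concept classes such as `Compound` or `Target`, edges carry
relation types such as `binds_to` or `similar_to`.  Skilled curators can spot
small portions of such a graph — *semantic subgraphs* — whose topology and
types are indicative of a drug-repositioning opportunity (for instance, a
compound structurally similar to a compound with a known target may bind
that target too).  Doing this by eye does not scale; `dresmin` does it
exhaustively.

Given a target network *G*, a semantic query subgraph *Q* and a user-set
semantic threshold *ST* ∈ \[0, 1\], the package returns **every** embedding
*M* of *Q* into *G* that

1. preserves topology and edge direction, mapping each query edge to a
   distinct target edge;
2. satisfies a **closed-world** rule: there is no additional edge between
   the mapped target vertices beyond those the query accounts for (the
   absence of an edge is treated as evidence of no relationship);
3. passes the semantic threshold, either **per element** (every vertex and
   edge pair scores ≥ *ST*) or **cumulatively** (the mean score does).

Semantic closeness is scored by a *semantic distance calculator* (SDC): two
square symmetric matrices over vertex and edge types, with entries

```
p_ij =  1   if type i is semantically identical to type j
        0   if unrelated
       -1   if opposite        (graded values in between are allowed)
```

and the *semantic score* of a mapping is the mean over its
n = |V(Q)| + |E(Q)| element pairs:

```
SS(M) = ( Σ_k SDC(m_k, q_k) ) / n          SS ∈ [-1, 1]
```

Each query can carry an *inference annotation* `(drug role, target role,
edge type)`: every embedding then infers a putative drug–target interaction
between the images of those roles.  Queries are scored by their ability to
recover known interactions (R<sub>q</sub> = fraction of a query's unique
inferences that are known), and each inferred interaction is ranked by the
cumulative score of the queries supporting it (R<sub>i</sub> = Σ R<sub>q</sub>).

## What is inside

* **Search** — a VF-style exhaustive depth-first backtracking matcher with
  an initial-candidate rule (start from vertices of an anchor type, usually
  `Compound`, with deg<sub>G</sub>(v) ≥ deg<sub>Q</sub>(v)), incremental
  closed-world pruning, and semantic thresholding
  (`search_graph()`, plus a `brute_force_search()` oracle for verification).
* **Semantic graph pruning** — removes target vertices semantically distant
  from every query vertex type before searching (`semantic_prune()`);
  loss-free in per-element mode.
* **Query splitting** — recursively splits queries with 4+ roles at their
  most connected vertex (the overlap node) into parts of ≤ 3 roles, searches
  the parts, joins partial mappings on the overlap node and re-checks the
  full contract (`split_once()`, `split_recursive()`, `split_search()`);
  returns exactly the un-split result, usually much faster.
* **Query derivation** — builds type-level query subgraphs from the shortest
  semantic paths between known drug–target pairs and deduplicates them by
  typed isomorphism (`shortest_semantic_path()`, `path_to_query()`,
  `dedup_queries()`, `derive_queries()`).
* **Ranking** — R<sub>q</sub> / R<sub>i</sub> scoring and deterministic
  ranking of inferred interactions (`score_query()`, `score_interactions()`,
  `rank_interactions()`).
* **Synthetic data** — seeded random semantic graphs with exact per-type
  vertex counts and per-metagraph-triple edge counts, random connected
  (optionally metagraph-consistent) queries, rigid-query planting for
  spiked-recovery experiments, and the chlorpromazine fixture
  (`random_graph()`, `random_query()`, `plant_instances()`,
  `chlorpromazine_fixture()`).
* **I/O and CLI** — GraphML and TSV graphs, JSON queries, TSV SDC matrices
  and reference pairs; `cmd_mine()` / `cmd_derive()` / `cmd_rank()` /
  `cmd_simulate()` / `cmd_oracle()` plus a thin `exec/dresmin` script with
  the matching subcommands.

## Worked example

The classic guilt-by-association case: chlorpromazine binds three annotated
targets, none of which explains its antihistaminic effect; it is
structurally similar to trimeprazine, which binds the Histamine H1 receptor.

```r
library(dresmin)

fx  <- chlorpromazine_fixture()
fx$graph
#> typed_graph: 6 vertices (2 types), 5 edges (2 types)
fx$query
#> query_graph: 3 roles, 2 edges, infers c1 -[binds_to]-> t1

sdc  <- identity_sdc(fx$graph$vertex_types, fx$graph$edge_types)
maps <- mine_query(fx$graph, fx$query, sdc, search_config(st = 0.8))
maps[[1]]$vertices
#>                      c1                      c2                      t1
#>        "chlorpromazine"          "trimeprazine" "Histamine H1 receptor"
maps[[1]]$ss
#> [1] 1

inf <- mappings_to_inferences(maps, fx$query)
ref <- data.frame(drug = "chlorpromazine", target = "Histamine H1 receptor")
rank_inferred_interactions(list(triad = inf), ref)
#>   rank           drug                target ri n_supporting_queries supporting_query_ids
#> 1    1 chlorpromazine Histamine H1 receptor  1                    1                triad
```

Exactly one embedding exists (every other candidate assignment violates
either the topology or the closed-world rule), it is semantically exact
(SS = 1), and the inferred pair recovers the known interaction, so the triad
query scores R<sub>q</sub> = 1 and the interaction R<sub>i</sub> = 1.

The same pipeline runs from the shell:

```sh
exec/dresmin mine --graph net.graphml --queries queries/ --out out \
    --st 0.8 --mode per-element --anchor-type Compound
exec/dresmin rank --inferences out/inferences.tsv --reference known.tsv --out ranked.tsv
```

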