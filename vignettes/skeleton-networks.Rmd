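---
title: "Skeleton networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelnet)
```

## The problem and the model

Molecular diagnosis of Mendelian disease increasingly leans on interaction
networks: genes causing the same disease tend to sit in shared complexes
and pathways, so a candidate variant gains credibility when its gene lies
on an interaction path between known disease genes. The obstacle is scale —
a whole human interactome has tens of thousands of nodes and over a million
directed, typed edges, far too much to inspect.

`skelnet` implements a reduction with a simple definition. Call the
clinically validated disease genes *drivers*, the set $D$. The **skeleton**
is

$$S \;=\; \bigcup_{(a,b)\,\in\,D\times D,\; a\neq b}\;
  \{\text{all minimal-length directed paths } a \to \dots \to b\},$$

taking both the nodes and the consecutive-pair edges of every such path.
Unreachable ordered pairs contribute nothing; a driver that reaches and is
reached by no other driver is excluded and reported as *unconnected*
(mitochondrially encoded genes are the classic real-world example — their
interactions with nuclear gene products are badly under-assayed).

The rest of the graph is organised in **levels** around the skeleton:
level $k$ adds every parent (in-neighbour) and child (out-neighbour) of a
level-$(k-1)$ node, plus all edges induced on the accumulated node set —
including the "curved" within-level links among the newly added nodes.
Expansion stops at **saturation**, the first step that adds no node; since
the node set is finite and strictly growing, this always terminates. A
node's level is therefore its first appearance, which equals its undirected
parent/child distance from the skeleton node set. Nodes never reached carry
no level: they exist only in the **whole graph**, among them isolated genes
and small self-referencing islands.

Three query types operate on the levelled graph: direct interactors of a
gene (within a level scope), all shortest directed paths between two genes,
and shortest connections from a gene to any node at level $\le k$. Because
the engine is directed while "is it connected?" is not, the third query
searches both orientations and reports them separately, tagged
outbound/inbound, never merged.

## Edge semantics

Edges are typed `physical`, `genetic` or `unknown`, and parallel edges
between the same ordered pair are kept when (and only when) their types
differ; each edge carries one or more evidence records (source database,
experiment system or evidence channel, optional reference such as a PMID,
optional score). Self-loops are allowed — self-association is common in
interaction data.

Paths are **node sequences**: a parallel physical+genetic pair between two
consecutive genes does not double the path count; instead every step of a
returned path lists the set of types present (`edge_types`). Shortest paths
are unweighted breadth-first distances — evidence scores describe
provenance confidence, not interaction length, so they do not weight the
search.

Degree conventions: each directed edge contributes one out-degree at its
source and one in-degree at its target; a self-loop contributes one of
each to the same node. Hence `avg_degree = 2E/N` and
`avg_in = avg_out = E/N` hold identically, which the test suite asserts on
every fixture. *Non-redundant interactions* count distinct unordered
endpoint pairs, collapsing direction and type; a self-loop counts as the
single pair $\{A,A\}$ (a choice we document rather than inherit, since
conventions differ).

## Source ingestion rules

Three tabular dialects are parsed, mirroring the shape of the major
interaction resources. All readers are TSV-with-header and
gzip-transparent; column layouts are frozen in the parser documentation and
shared with the fixture generator.

* **Curated experiment tables** (BioGRID-like): rows where either
  interactor's taxon differs from the requested one are dropped (these
  databases include artificial trans-species assays). The interaction type
  comes from an explicit physical/genetic label when present; otherwise it
  is *deduced from the experiment system* through a configurable
  two-set map (e.g. two hybrid, FRET, co-crystal structure ⇒ physical;
  dosage lethality, dosage rescue ⇒ genetic). Systems in neither set yield
  `unknown` — never a guess. Physical and unknown records are treated as
  bidirectional and emit two directed edges; genetic records are taken as
  unidirectional in listed order and emit one.
* **Protein links with evidence channels** (STRING-like): records whose
  score is zero across the evidence channel set (default
  `{experimental, database}`, configurable) are discarded as
  prediction-only. An optional actions table supplies per-pair direction
  tags; untagged pairs emit both directions. Links are typed `physical` —
  they describe protein–protein association. Each qualifying channel
  becomes one evidence record with its score.
* **Text-mining output** (PPaxe-like): records are filtered by classifier
  score (default threshold 0.5, a parameter the caller owns) and by
  official-nomenclature membership of both symbols after alias resolution —
  text mining is the noisiest source and the one that benefits most from
  the nomenclature gate. No direction is inferred, so both directed edges
  are emitted, typed `unknown`, each carrying the supporting PMID.

Before graph construction every symbol is rewritten to its official form
through a case-insensitive alias table (text-mined symbols are frequently
case variants). Edges that collapse onto the same `(src, dst, itype)` merge
with concatenated evidence, so unaliasing is idempotent and conserves the
evidence records of surviving edges. Unresolvable non-driver symbols are
dropped by default (withdrawn or junk identifiers would otherwise pollute
the node set); an unresolvable *driver* is a fatal error, because the
skeleton would silently lose a seed.

## Numerical and algorithmic choices

* **Skeleton membership without path enumeration.** The number of shortest
  paths can grow combinatorially, but their union cannot: with forward BFS
  distances $d_a$ from $a$ and backward distances $d^b$ to $b$, node $v$
  lies on a shortest $a\to b$ path iff $d_a(v) + d^b(v) = d_a(b)$, and edge
  $u \to v$ iff $d_a(u) + 1 + d^b(v) = d_a(b)$. Two BFS runs per driver
  suffice for the whole skeleton.
* **Deterministic output.** Adjacency lists are kept sorted, enumerated
  paths are sorted lexicographically by node symbols (C-locale radix
  order), and all-path enumeration caps at `max_paths` (default 1000 in
  queries) with an explicit truncation flag, so results are reproducible
  and bounded on dense graphs.
* **Degenerate inputs.** A query with `gene_a == gene_b` returns the single
  zero-length path rather than erroring; an unreachable target returns an
  empty table (with a hint to try the reverse direction); a skeleton needs
  at least two drivers; an empty edge list with drivers yields isolated
  driver nodes.
* **Level-0 edge tally.** Level edge sets for $k \ge 1$ are induced-edge
  sets. We apply the same rule at level 0 so that per-level totals always
  reconcile exactly with the whole graph (induced edges among skeleton
  nodes that lie on no driver-pair path would otherwise be counted
  nowhere); the stricter shortest-path edge subset remains available as
  `skeleton_result$edges`. This is the one place the bookkeeping deviates
  from the narrowest reading of "skeleton edges", and it is deliberate.
* **Unconnected drivers still take part in expansion**: they are excluded
  from the skeleton but, if they have any interactions, the shells will
  reach them like any other node; `unconnected_drivers` is reported
  separately so neither fact hides the other.

## Annotation, sessions and exports

Annotation layers are generic named numeric maps (expression summaries,
fold changes, variant counts) projected onto nodes with a per-layer default
for missing genes; attaching is idempotent and never touches topology
(asserted by hashing the typed edge multiset). Sessions persist a subgraph
with exact layout positions; coordinates are serialized at 17 significant
digits, which round-trips IEEE doubles bit-exactly, so a reloaded network
is laid out exactly as it was left. Session edge records keep their full
evidence lists — a summary would be lossy and break the round-trip-identity
contract. Exports (Cytoscape.js elements JSON, GraphML via igraph,
edge-list TSV, Neo4j bulk-import CSVs) are pure functions of the graph.

## The synthetic-fixture generator

Real interactome releases are huge, versioned and unavailable offline, so
correctness is established on synthetic data with known ground truth. The
generator (`fixture_spec()` / `generate_fixture()`) emulates all three
source dialects at once from a single record list, then writes the files
*with deliberate contamination*: a fraction of genes appear under aliases,
plus injected non-human rows, evidence-free protein-links rows, and
below-threshold or non-official text-mining rows that parsers must drop.

The graph model is a directed Erdős–Rényi backbone over undirected
interaction records (defaults: 30 genes, edge probability 0.06, 20%
genetic, 15% unknown/text-mining, 10% alias rate, 2 isolated genes) plus
planted driver-to-driver chains of chosen lengths through fresh
intermediate genes, so known shortest paths exist by construction. Defaults
were chosen once to give sparse-but-connected graphs with the qualitative
features of a curated disease interactome (mixed sources and types, early
saturation, a few unconnected genes); they are deliberately small —
statistically realistic degree distributions (scale-freeness) are a
non-goal. Ground truth in the manifest is computed through igraph distance
matrices — a code path independent of the package's own BFS machinery —
and the test suite adds a second, pure-R brute-force enumeration oracle.
What passing these tests shows is that the algorithms implement their
definitions exactly; what they cannot show is robustness to the quirks of
any particular database release (column drift, encoding issues, identifier
churn beyond simple aliasing).

## Problem sizes used in checks

Oracle-equivalence checks run on 200 random digraphs of up to 12 nodes
with 2–5 drivers each (exhaustive enumeration is only tractable at this
size, and disagreements, if any, do not require large graphs to surface);
parser contracts on 50 generated fixtures of 18 genes; the end-to-end
reproduction script on a 300-gene, 20-driver synthetic interactome with
planted chains of lengths 1–4, sized so the whole pipeline — generation,
parsing, skeleton, levels, queries — completes in seconds while exhibiting
multi-level saturation.

## Known limitations

* Shortest paths are unweighted; confidence-weighted search is out of
  scope by design.
* The alias table is a static two-column file; live nomenclature lookups
  are not performed.
* Level semantics treat parent/child expansion as undirected reachability
  (both orientations), which matches the "parents and children" definition
  but means levels do not encode directionality.
* The generator's networks are small and Erdős–Rényi-shaped; conclusions
  about performance or statistics on million-edge interactomes should be
  drawn from the algorithmic complexity (BFS per driver, linear merges),
  not from the fixtures.

## Worked example

```{r}
wex <- worked_example()
g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
sk <- build_skeleton(g)
lv <- expand_levels(g, sk)
lv
g <- set_levels(g, lv)
query_paths_between(g, "DRV3", "DRV2", level_cap = 0)
glance(lv)
```
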