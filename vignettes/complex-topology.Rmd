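---
title: "Profiling protein-complex topology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protein-complex topology: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complextopo)
```

## The model

A binary interaction network is a simple undirected graph: proteins are
vertices, reported pairwise interactions (e.g. from yeast two-hybrid
screens) are edges. Duplicate reports collapse to one edge and
self-interactions are dropped on ingest, because every statistic the survey
computes assumes a simple graph. Degree-0 vertices are legitimate — a
protein can be assayed without any reported partner — and are kept in the
vertex set.

A complex is a named member set, optionally with *reference edges*: internal
interactions determined by a reliable method such as X-ray crystallography.
The survey asks how a complex looks *inside the network*: its graph is the
subgraph induced by the members present, with all network edges among them.
Members absent from the network are dropped rather than added as isolated
vertices — the network defines the observable universe, and padding with
unobservable vertices would deflate density and degree denominators in a way
no complex-finding algorithm operating on the network could see. The
fraction of members present is reported separately as `coverage`.

## The statistics

For each graph the profile reports:

* **Vertex / edge connectivity.** The largest $k$ such that every vertex
  pair is joined by $k$ vertex-disjoint (edge-disjoint) paths; 0 for
  disconnected graphs and singletons, $n-1$ for the complete graph. The
  motivation: in a densely packed complex each protein binds a bounded
  number of neighbors, so density must fall as size grows, but connectivity
  can stay constant.
* **Edge density** $m / \binom{n}{2}$; undefined below 2 vertices.
* **Degree summary** (max, min, mean, population sd), divided by $n$
  exactly — not $n-1$ — when normalized, so the normalized maximum is
  always $< 1$.
* **Clustering coefficient** $3T/P_2$ with $T$ the triangle count and
  $P_2 = \sum_v \binom{\deg v}{2}$ the number of length-2 paths. When
  $P_2 = 0$ the ratio is undefined; we return 0 with a `defined = FALSE`
  flag rather than erroring, so profiles of tiny graphs stay tabulable, and
  flagged values are never counted as passing a sweep threshold.
* **Mutual clustering coefficient** of a pair: shared neighbors divided by
  the smaller degree. The shared-neighbor set cannot contain the endpoints
  themselves in a simple graph. Pairs where either endpoint has degree 0
  are *excluded* from the summary rather than scored 0 — scoring them would
  mean dividing by zero, and excluding them matches the reading that MCC is
  about proteins that do interact with something.
* **Motif counts.** Triangles as distinct 3-cliques; 4-cycles as distinct
  simple (not necessarily induced) quadrilaterals, each counted once, via
  $\tfrac12 \sum_{\{u,v\}} \binom{|N(u) \cap N(v)|}{2}$ — every 4-cycle is
  counted once per diagonal pair. Both formulas are verified in the test
  suite against exhaustive subset enumeration.
* **Betweenness.** The per-vertex count of shortest paths between other
  pairs through the vertex is ambiguous when several equal-length paths
  exist, so we adopt the standard fractional convention (each $s$–$t$ pair
  contributes the fraction of its shortest paths through $v$; endpoints
  excluded) and normalize by $n$ like degree. Betweenness is only defined
  for connected graphs with at least 3 vertices; elsewhere it is NA-marked,
  never fabricated.

All summary statistics use the population (divide-by-count) standard
deviation, and values are kept at full precision until serialization.

## Subgraph variants

Each complex is profiled three ways. The **full graph** is the induced
graph above. The **haircut** recursively deletes all vertices of degree
$\le 1$ — including isolated vertices — until the remainder has minimum
degree $\ge 2$ or is empty; the operation is idempotent and can never
destroy a triangle, which is why clustering coefficients typically rise
under it. The **MHCS** (most highly connected subgraph) is an induced
subgraph on $\ge 3$ vertices attaining the maximum vertex connectivity over
all such subgraphs; 2-vertex subgraphs are excluded because any single edge
is trivially 1-connected and the object would be meaningless. Connected
components are profiled as a fourth, pooled series.

### The MHCS search

The search is recursive minimum-cut splitting. For each connected candidate
with $\ge 3$ vertices: record its connectivity $\kappa$; find one minimum
vertex cut $C$; recurse into every component $H$ of $G - C$ induced
together with $C$. The search is exact for the achieved $k$: if a subgraph
$H^\*$ has $\kappa(H^\*) > |C|$, then $C \cap V(H^\*)$ cannot separate
$H^\*$, so $H^\*$ minus $C$ lies inside a single component of $G - C$ and
$H^\*$ survives into that branch; if $\kappa(H^\*) \le |C| = \kappa(G)$,
recording $G$ itself already attains it. Recursion stops at complete
graphs.

Two refinements keep this fast without giving up exactness in $k$: branches
are reduced to their $(k_{best}+1)$-core before splitting (a $k$-connected
subgraph has internal minimum degree $\ge k$, hence lives in the $k$-core),
and branches whose core vanishes are pruned. Ties are broken
deterministically — higher $k$, then more vertices, then the
lexicographically smallest sorted vertex-name list — among the candidates
the search encounters; with pruning, an equally-connected but larger
candidate in a pruned branch may be passed over, so only the value of $k$
(not the identity of the returned subgraph) is guaranteed maximal. The test
suite checks $k$ against exhaustive enumeration over all vertex subsets on
hundreds of random graphs of up to 8 vertices.

## Null models

**Switching** randomizes the whole network while preserving every vertex's
degree: choose two random edges $(A,B)$ and $(C,D)$, and replace them with
$(A,D)$ and $(C,B)$. Because stored edge orientation is arbitrary in an
undirected graph, the implementation flips the second edge's orientation
with probability $\tfrac12$ before rewiring, so both pairings are
reachable and the walk is unbiased. A proposal is rejected — and not
counted — if the four endpoints are not distinct or a replacement edge
already exists, so the result is always simple. For a network with $n$
vertices, $100n$ *successful* swaps are performed (mixing is cheap relative
to profiling, and counting successes is the stricter reading); a proposal
cap of 1000 times the target guarantees termination on graphs with no valid
swap, such as cliques, which are returned unchanged. Ten replicate networks
form the default comparison ensemble, each seeded deterministically from
the configuration seed and the replicate index.

**Pseudocomplexes** answer the per-complex question "how likely is this
profile in a complex-free region of the same network?". A pseudocomplex of
size $n$ starts from a uniformly random edge of a uniformly random triangle
(triangle-seeding makes the null conservative: most real complexes contain
a triangle, and the seed biases samples toward a 2-connected core). It then
grows by drawing a uniformly random network edge with exactly one endpoint
inside the current set and absorbing the outside endpoint *with all its
edges into the set* — sampling edges rather than neighbors makes
multiply-connected vertices proportionally more likely to join, keeping the
sample complex-like. Growth that exhausts its component restarts from a
fresh triangle, up to 50 times. Only complexes with at least 4 members
*present in the network* (matching is on the observable graph, not nominal
membership) and at least one induced edge are matched; the default is 100
pseudocomplexes per complex, which stabilizes the pseudo means and standard
deviations at modest cost — the source data for the comparison reports
both.

## The synthetic study

The generator stands in for the composite Y2H network plus the
membership-only and reference complex catalogs. Its default spec — the
conditions used by the package's own tests and acceptance script — is:

* a 500-vertex background with degrees drawn from a discrete power law
  (exponent 2.5, minimum degree 1, inverse-transform sampled and floored),
  realized by the configuration model and simplified; a heavy-tailed sparse
  background is the regime in which triangle seeding and boundary-edge
  growth behave as they do in real PPI data;
* 20 planted ring-lattice complexes with binding width $b = 2$ and sizes
  evenly spread over 6–30. The ring lattice is the minimal realization of
  the steric-constraint picture: every member binds its $2b$ nearest
  neighbors, so density $2b/(n-1)$ falls with size while connectivity stays
  at $2b$. Clique and hub-and-spoke wirings are available for contrast;
* 1–3 uniformly chosen bridge edges per complex tying it to the background,
  so pseudocomplex growth can traverse complexes as it does in a real
  composite network;
* an observation layer with a 10% false-negative rate (each true edge
  dropped independently) and a 5% false-positive rate. False positives are
  parameterized relative to the *true edge count* (drawn Poisson, inserted
  as uniformly random non-adjacent pairs) rather than per non-edge pair,
  which would grow quadratically and destroy sparsity at scale. The rates
  reflect the common reading of Y2H error structure: false negatives
  dominate; false positives are real but secondary.

Membership lists are emitted pre-noise — catalog knowledge concerns
membership, noise lives on edges — and the truth list carries each
complex's pre-noise internal edges, the crystallography analogue used by
`reference_overlap()`.

What the generator does **not** emulate: the empirical BioGRID degree
distribution (only its heavy tail), correlated or systematic assay error
(sticky proteins, bait/prey asymmetry), overlapping complexes sharing
members, and mass-spectrometry spoke/clique expansion artifacts. Tests
passing on this generator therefore show the pipeline's statistics behave
as designed under the stated structural assumptions — not that any
particular biological catalog will separate as cleanly.

## Reproducibility and numerical choices

All randomness flows from explicit integer seeds; replicate and
per-complex streams are derived from the configuration seed with fixed
prime offsets, so ensembles and matched samples replay identically.
Component ordering, MHCS tie-breaks, and serialized column order are
deterministic, and two runs of the pipeline from the same seed produce
byte-identical output tables.

Threshold sweeps read "above" as $\ge$ and "below" as $\le$ (betweenness is
swept downward, since complexes are expected to lack bottleneck vertices).
Default grids are 0–1 in steps of 0.1 for the unit-interval statistics and
$k \in \{1,\dots,6\}$ for connectivity. Undefined values stay in the
denominator of a sweep percentage but never pass a threshold; complexes
that induce no edge at all are excluded from sweeps entirely and listed
separately.

Problem sizes in the test suite were chosen to exercise every code path at
desk scale: exhaustive oracles run on 200 random graphs of at most 8
vertices (where brute force over all vertex and edge subsets is feasible),
haircut contracts on 500 random graphs, switching ensembles on a
~300-vertex study, and the separation analysis on the full default study
(20 complexes, 100 pseudocomplexes each).

## Known limitations

* The separation between real complexes and pseudocomplexes is a
  *distributional* statement. Individual seeds can and do produce haircut
  graphs with an articulation point (connectivity 1) under edge noise —
  degree peeling does not guarantee 2-connectedness; the observation that
  it almost always delivers it is an empirical property of complex-like
  wiring, not a theorem.
* `min_separators`-based splitting can be expensive on large dense graphs;
  the MHCS search is intended for complex-sized graphs (tens of vertices),
  not for whole networks.
* The pseudocomplex null requires at least one triangle in the network and
  cannot match complexes larger than their host component.
* Betweenness, CC and MCC conventions follow the definitions above; other
  conventions (endpoint-inclusive betweenness, per-vertex clustering) are
  deliberately out of scope.
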