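---
title: "Multilevel gamma-clustering for structural network visualization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel gamma-clustering for structural network visualization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaclust)
library(igraph)
```

## The problem

Large biological networks — metabolic reaction networks, gene
co-expression networks, protein interaction networks — are dense: a few
thousand nodes can carry tens of thousands of edges, most of them inside
tightly knit modules. Drawn directly with a force-directed layout, the
modules collapse into hairballs and the global organisation of the system
is unreadable. `gammaclust` takes the opposite route: analyse the
structure first, then draw a *summary* of it. The pipeline has three
phases:

1. **Multilevel γ-clustering.** Dense subgraphs (quasi-cliques) are
   detected and replaced by cluster nodes, recursively, producing a
   layered hierarchy.
2. **Tree transformation.** The hierarchy is reduced to a rooted
   shortest-path tree from a hidden root; every edge not on such a path
   is hidden (but retained for drill-down queries).
3. **Hierarchy-aware layout.** The tree is drawn with a force-directed
   layout whose target edge lengths grow with the hierarchy level, after
   a concentric-circle initialisation.

Because a cluster of $k$ nodes holds up to $\binom{k}{2}$ edges but is
drawn as one glyph with $k$ membership spokes, the default view removes
the bulk of the edges while two queries (`highlight_neighbors()`,
`cluster_internal_edges()`) recover any hidden detail on demand.

## γ-clusters

For an undirected simple graph $G=(V,E)$ and $S \subseteq V$ with induced
edge set $E(S)$, $S$ is a **γ-cluster** (γ-clique, quasi-clique) when

$$|E(S)| \;\ge\; \gamma \binom{|S|}{2}, \qquad 0 \le \gamma \le 1 .$$

γ = 1 recovers cliques; smaller γ tolerates missing edges. Finding a
maximum-cardinality γ-cluster is NP-hard (it contains maximum clique), so
detection uses a GRASP heuristic — a greedy randomized adaptive search
procedure — while `max_gamma_clique_exact()` provides an exhaustive
oracle for graphs of ≤ 20 nodes that the test suite uses to audit the
heuristic.

Sets of size 0 or 1 are assigned density 1 by convention; it is the
minimum cluster size (`min_size`, default 3), not the density test, that
excludes trivial sets.

### The construction heuristic

Each GRASP restart:

1. **Seeding.** A start vertex is drawn uniformly from the top
   `rcl_alpha` fraction (default 0.2) of vertices by degree — the
   restricted candidate list.
2. **Greedy growth.** Among candidates adjacent to the current set $S$,
   the vertex with the most links into $S$ is added (ties broken at
   random, which is where restarts gain diversity), subject to two
   admission conditions:
   * the potential $\varphi(S) = |E(S)| - \gamma\binom{|S|}{2}$ must stay
     non-negative, and
   * the entering vertex $v$ must satisfy $\mathrm{conn}(v, S) \ge
     \kappa\,\gamma\,|S|$ with slack constant $\kappa = 0.75$.
3. **Peeling.** Members falling below the same per-vertex line,
   $\mathrm{conn}(u, S\setminus u) < \kappa\,\gamma\,(|S|-1)$, are removed
   worst-first, as is any member while $\varphi < 0$.
4. **Swap local search.** While it strictly raises $\varphi$, the worst
   member is traded for the best outsider, followed by renewed growth and
   peeling.

A set is returned only if $|S| \ge$ `min_size` and $\varphi(S) \ge 0$ —
the exact density bound is always re-checked, so every emitted cluster
satisfies the γ-cluster inequality by construction. Across restarts the
best cluster wins: largest, then densest, then lexicographically
smallest.

**Why the per-vertex condition?** A density-only greedy rule returns the
maximum-cardinality quasi-clique, which is the wrong object for
structural summarisation. The canonical failure is two cliques joined by
a perfect matching: two $K_8$ plus a matching have global density
$64/120 \approx 0.53$, so at γ = 0.5 the *whole graph* is a γ-cluster and
a purely density-guided search merges the two modules — precisely the
structure the method exists to separate (a minimum-spanning-tree
preprocessing fails on the same case by collapsing one clique onto a
single path). Requiring each member to carry roughly its share of the
density (κγ per possible neighbour) keeps sparsely attached appendages
out while the slack κ < 1 tolerates members of a genuinely dense block
whose degree sits slightly under the γ line; κ = 1 was observed to shave
legitimate members off planted blocks (a Binomial(9, 0.9) in-degree dips
below 0.7·9 with probability ≈ 0.05 per node), while κ ≤ 0.5 readmits
matching bridges. The value 0.75 splits that range and is fixed, not
user-tunable.

### Extracting all clusters of a level

`create_clusters()` repeatedly runs the construction, removes each found
cluster's members from the candidate pool, and stops when no cluster of
at least `min_size` members remains. Extraction on induced subgraphs can
only *lose* edges among remaining vertices, so clusters later in the
sequence also satisfy the density bound in the full level graph.
Clusters are therefore vertex-disjoint, which the membership edges of the
hierarchy presuppose.

## Hierarchy creation

All input nodes start at level 0. One clustering pass over the current
top level adds a layer: a **cluster node** per cluster (`C<level>_<i>`),
a **membership edge** from the cluster node to each member, and an
**inter-cluster edge** between two cluster nodes whenever *any* edge runs
between their member sets one level below. The next pass clusters the
induced graph of the new cluster nodes with the next scheduled γ, and the
recursion stops when a level yields no cluster — or a single one, since
nothing is left to merge.

The γ schedule grows with the level (default `c(0.5, 0.7)`, last value
repeating): induced density rises as the hierarchy is ascended, so a
looser first level captures broad modules while subsequent levels demand
tighter structure. A non-growing schedule triggers a warning, not an
error.

Nodes a level's extraction leaves unclustered do not participate in
higher levels; they remain reachable through their original edges when
the tree is built. The alternative — letting stragglers join later
levels — would blur the meaning of a level-$i$ cluster node as a
γᵢ-dense group of level-$(i-1)$ objects.

## Tree transformation

A hidden root (kind `root`, never drawn) is attached to every top-level
cluster node. Breadth-first search from the root over the *full* layered
graph (base, inter-cluster and membership edges alike) assigns every
reachable node its distance; each node keeps exactly one parent:

* a cluster member's parent is **its own cluster node** — even when a
  neighbour in another cluster is equally close — so clusters render as
  stars around their glyph;
* otherwise a uniformly random choice among neighbours one step closer
  (one seeded generator shared across the pass, so a seed fixes the whole
  tree).

The membership override never violates BFS optimality: an inter-cluster
edge witnesses every member-to-other-cluster adjacency, so the cluster
node is always at least as close to the root as any foreign neighbour.
The test suite asserts this rather than assuming it.

Components containing no cluster at all are unreachable from the root.
Their nodes attach directly to the root with synthetic edges and are
flagged as orphans so the renderer can style them; they are excluded from
the BFS graph, which keeps reachable depths equal to true BFS distances.

Tree edges and `hidden_edges()` partition the layered graph's edge set
exactly (orphan attachments excepted, as they exist only in the tree);
this partition is what makes the drill-down operations lossless.

## Layout

`initial_positions()` places the root at the area centre and depth-$d$
nodes on circle $d$; each node receives an angular segment inside its
parent's, split among siblings proportionally to subtree leaf counts so
large subtrees get room, and sits at its segment's bisector. A seeded
jitter of at most $10^{-6}\,\times$ `base_edge_length` breaks exact
overlaps on symmetric trees. This initialisation already reflects the
tree topology, so the force phase refines rather than untangles.

`force_layout()` then iterates:

* **Springs** along tree edges with force $k_s\,(d - \ell_0)$,
  $k_s = 0.08$. The target length of an edge is
  `base_edge_length * level_factor^level` (level = the deeper endpoint's
  hierarchy level; root edges take the top level), so higher-level edges
  are drawn longer and the hierarchy reads outward from the centre.
* **Repulsion** $q/d^{2}$ (as a displacement along the separation vector)
  between all pairs within the cutoff distance
  `repulsion_cutoff_fraction * min(width, height)` (default fraction
  0.25); beyond it, repulsion is zero, which also stops disconnected
  pieces from drifting apart. $q = (0.35\,\times$
  `base_edge_length`$)^2$. Spring rest lengths are shortened to
  $\ell_0 = \ell - q/\ell$ so an isolated edge equilibrates at exactly
  its target length $\ell$ despite the residual repulsion between its
  endpoints.
* **Damping**: each node's displayed position is the mean of its last
  `damping_window` (default 3) raw positions — the standard cure for the
  oscillation of force-directed iterations.
* Steps are clamped to half a base edge length, positions are clipped to
  the drawing area every iteration (coordinates can never become
  non-finite), and iteration stops when the largest displacement falls
  below `convergence_tol` or at `max_iterations`. The `converged` flag
  reports which.

All constants above are implementation choices held fixed by the test
suite, not claims about any reference implementation; the classic
force-directed literature leaves them free.

## Rendering and drill-down

The SVG renderer draws one element per visible node and tree edge: base
nodes as dots coloured by their degree *in the original graph*, cluster
nodes as diamonds growing linearly with level, the root omitted. Degree
colours bin the distinct degree values into quantile bins (default 5)
over an ordered palette, so a single hub of a skewed degree distribution
still lands in the top bin. Output is byte-deterministic (fixed number
formatting, sorted element order), which makes end-to-end reproducibility
testable with a file comparison.

`highlight_neighbors()` returns, for a base node, its original incident
edges; for a cluster node, all hierarchy edges incident to the glyph plus
original edges from members to non-members. `cluster_internal_edges()`
returns the level-below edges among a cluster's members (original edges
for level 1, inter-cluster edges above). Together with the cross-cluster
and orphan edges, these reconstruct the original edge set exactly — the
tests assert the reconstruction edge-for-edge.

## Correlation networks

`correlation_network()` builds a gene co-expression graph: nodes are
genes, and an edge joins two genes when their Pearson correlation across
samples is strictly above the threshold (an edge marks correlation
*above* the cutoff; `strict = FALSE` switches to ≥). Negative
correlations do not create edges unless `use_absolute = TRUE`.
Zero-variance genes have undefined correlations and never gain edges;
isolated genes are dropped by default. Raising the threshold can only
shrink the edge set — `edge_count_monotonicity()` exposes this as a
property-test helper. Typical thresholds for expression compendia sit in
the 0.7–0.8 range; 0.72 is the pipeline default.

## Synthetic benchmarks

The generators in this package define the conditions under which the
pipeline is tested, and every generator is a pure function of its
parameters and seed:

* `planted_partition()` — Bernoulli blocks (defaults used in the tests:
  3 blocks × 10 nodes, $p_{in} = 0.9$, $p_{out} = 0.02$), the standard
  ground-truth model for cluster recovery. Recovery is scored by Jaccard
  overlap with the planted blocks.
* `cliques_joined_by_matching()` — the pathological structure discussed
  above; tests demand the two $K_8$ come back exactly.
* `scale_free_graph()` — preferential attachment emulating the skewed
  degree distributions of biological networks. Convention: a star seed
  on $m+1$ nodes, then $m$ distinct degree-proportional targets per new
  node, giving exactly $m(n-m)$ edges.
* `synthetic_expression()` — one latent factor per gene block plus
  Gaussian noise; with noise σ the within-block correlation attenuates
  to $1/(1+\sigma^2)$, which the tests verify at σ = 0.1.

What these fixtures do *not* emulate: overlapping modules, hierarchically
nested modules of heterogeneous density, degree-corrected blocks, and
measurement artefacts of real expression compendia. Passing tests
therefore demonstrate correct mechanics and recovery under clean planted
structure, not performance guarantees on arbitrary real data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on graphs of up to ~200
nodes and expression matrices of up to a few dozen genes — sizes chosen
so the whole suite exercises every code path, including the exhaustive
oracle, in well under two minutes on a laptop-class machine. The
algorithms themselves are polynomial per level (the construction is
$O(\mathrm{restarts} \cdot \sum_v \deg v)$ per extracted cluster) and
have no fixed size ceiling apart from `max_gamma_clique_exact()`'s
20-node guard.

Ties everywhere are broken deterministically (lexicographic member
order) or by the stage's seeded generator; every stage seed derives from
the single pipeline seed by fixed offsets, so one integer reproduces an
entire run byte-for-byte.

## Known limitations

* Clusters are disjoint; overlapping quasi-cliques are out of scope, and
  a vertex shared between two dense modules is assigned to whichever
  cluster is extracted first.
* The per-vertex admission rule makes the detector deliberately
  conservative: it prefers cohesive clusters over maximum-cardinality
  quasi-cliques, and near the feasibility boundary (e.g. two $K_6$ joined
  by a matching at γ = 0.5, where the whole graph is both γ-dense and
  κγ-cohesive) it may legitimately return the merged set.
* Graphs are unweighted and undirected; weights in input files are
  ignored with a warning.
* The layout is $O(|V|^2)$ per iteration due to pairwise repulsion; for
  drawings beyond a few thousand visible nodes a spatial index would be
  the natural next step.
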