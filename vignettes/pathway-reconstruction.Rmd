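---
title: "Reconstructing pathways with k shortest loopless paths"
author: "kspathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pathways with k shortest loopless paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspathway)
```

## The problem

Signaling pathways are curated as small, high-confidence diagrams, but the
interactions that actually carry a signal from the cell surface to the
nucleus are embedded in a genome-scale interactome of physical and
regulatory interactions. Given such a background network, a set of *source*
nodes (typically receptors) and a set of *target* nodes (typically
transcription factors), `kspathway` reconstructs the connection between the
two sets as the union of the *k* best-scoring **loopless** directed paths
from any source to any target. A loopless (simple) path visits every node at
most once. Returning many near-optimal paths rather than one shortest path
is the point: a single shortest path is fragile to weight noise, whereas the
union of the top *k* paths recovers a sub-network whose size the analyst
controls directly through *k*.

The method is generic — any directed, optionally weighted network and any
two node sets work — but the defaults are chosen for protein interaction
networks whose edge weights are experimental-reliability probabilities.

## Edge weights, costs and scores

All search machinery minimises an **additive internal cost** per edge,
derived from the user-facing weight by the mode set in `cost_config()`:

| mode | edge cost | path score | best path |
|---|---|---|---|
| `unweighted` | $1$ | number of edges | fewest edges |
| `additive` | $w + p$ | $\sum w$ | smallest sum |
| `probability` | $|\log w| + \log p$ | $\prod w$ | largest product |

with $w$ the raw weight and $p \ge 0$ (probability mode: $p \ge 1$) the
**edge penalty**. Probability weights must lie in $(0, 1]$, so
$|\log w| = -\log w$ and minimising the summed cost maximises the product of
reliabilities. The penalty adds a constant surcharge per edge (after the log
transform in probability mode), which biases the ranking toward shorter
paths; its default is 1 for probability weights (no penalty, since
$\log 1 = 0$) and 0 otherwise. Natural logarithms are used; the ranking is
invariant to the base and the reported score is the raw product, so the
choice is unobservable externally — it is documented so internal cost values
are reproducible. Reported path scores always exclude the penalty: the
penalty shapes which paths are chosen, not how they are described.

Weight validation is strict: probability weights of 0 (infinite cost) or
above 1, negative additive weights (Dijkstra/A* assume non-negative costs)
and mixed weighted/unweighted edge lists are rejected at load time.

## The engine

`run_pathlinker()` executes the pipeline:

1. **Endpoint validation.** Absent endpoints are skipped with a warning (the
   non-interactive analogue of confirming a "continue with the remaining
   nodes" dialog); `strict = TRUE` aborts instead. If no source or no target
   survives, the run aborts.
2. **Query graph.** Unless `allow_sources_targets_in_paths = TRUE`, edges
   into sources and out of targets are removed, so endpoints can only open
   or close a path. A super source $s^\*$ gains zero-cost edges to every
   source and every target gains a zero-cost edge to a super target $t^\*$,
   reducing the set-to-set problem to the single pair $(s^\*, t^\*)$. Super
   edges cost exactly 0 in every mode, so neither internal costs nor
   reported scores ever count them — in unweighted mode the score of a path
   is the number of *real* edges.
3. **Heuristic.** One Dijkstra pass that *traverses in-edges* from $t^\*$
   (`reverse_dijkstra()`) yields, for every node, the exact cost-to-target
   on the full graph — without materialising a reversed copy of the network.
4. **Yen's algorithm with A*** (`yen_ksp()`). The i-th accepted path is
   deviated at every spur position: the nodes of the root prefix and the
   next edge of every previously accepted path sharing that prefix are
   *hidden* — masked, not deleted, so restoring them is free — and an A*
   search from the spur node proposes a candidate. Looplessness is enforced
   by the hiding itself, by construction. The heuristic from step 3 is
   computed once and reused for every spur search: hiding elements can only
   lengthen true distances, so it remains an admissible (indeed consistent)
   lower bound. With the heuristic the search expands only nodes on
   near-optimal corridors, which is what makes large *k* on large networks
   practical.
5. **Assembly.** Super nodes are stripped, raw-weight scores attached,
   paths ranked 1..n, and the sub-network assembled with **first-path
   indices**: every node and edge is annotated with the rank of the first
   path containing it, the standard way to order reconstructed pathway
   elements by confidence.

The returned costs carry a guarantee Yen's construction provides: no
loopless source-to-target path has cost strictly between two consecutive
returned costs.

### Determinism and ties

Paths of equal cost are ordered by the total order *(cost, number of edges,
lexicographic node sequence)*, applied identically in the candidate pool, in
the A* search and in the brute-force oracle, so every result is
reproducible across runs and platforms. Three numerical choices make the
agreement *exact* rather than approximate:

* costs are compared as floating-point values with no epsilon;
* every candidate path's cost is recomputed as the strict left-to-right sum
  of its edge costs, so the same path always yields the same float no
  matter which spur produced it;
* lexicographic comparison of node identifiers uses C-locale byte order
  (radix order), independent of the session locale.

Inside A* the tie order is enforced by a label-correcting refinement: a
node's label is replaced whenever a strictly smaller (cost, hops,
lexicographic) label appears and re-enters the queue, so the search
converges to the canonical optimum for any admissible heuristic — the
all-zeros heuristic (plain Dijkstra) provably returns the identical path
set, which the test suite checks instance by instance.

### Degenerate queries

With `targets_are_sources = TRUE` every shared endpoint $v$ induces the
trivial two-super-edge path $s^\* \to v \to t^\*$ containing no real edge.
The engine is kept pure: the pipeline requests $k + |S \cap T|$ paths and
drops stripped paths with fewer than two nodes. A single self-connected
node therefore yields zero paths — a loopless path cannot revisit its own
start.

## The through-node baseline

`strongest_paths()` implements the through-node shortest-path procedure
used by slider-threshold apps: forward Dijkstra from $s^\*$, reverse
Dijkstra from $t^\*$, per-node $d(v)$ = cheapest source-to-target cost
through $v$, and emission of the through-$v$ path for every $d(v) \le a +
\tau$ where $a = \min_v d(v)$. Because at most one path is emitted per
node, at most $n$ distinct paths can ever be returned; the package ships a
3×3 layered-grid fixture with nine equal-cost paths and eight nodes on
which the baseline provably misses a path of optimal cost — the limitation
that motivates ranking paths rather than nodes. Two local policies the
procedure itself leaves open: a through-node path whose forward and
backward chains collide (repeat a node) is discarded with a warning, and
ties in $d(v)$ are ordered by node identifier.

## Synthetic networks and the oracle

`generate_network()` produces Erdős–Rényi-style directed graphs without
self-loops, with either a per-pair edge probability or an exact edge count,
and weights drawn uniformly — $(0, 1]$ for probability mode, $(0, 10]$ for
additive — rounded to 6 decimals so edge lists are platform-stable as text.
The generator reproduces byte-identical networks from a seed and restores
the caller's RNG state. It emulates *size and density only*: real
interactomes are scale-free, locally clustered and weighted by curated
evidence models, none of which a uniform random graph shows. Passing the
oracle properties on these instances therefore demonstrates algorithmic
correctness — optimality, completeness, ordering, determinism — not
biological validity of any particular reconstruction.

`enumerate_all_paths()` is the ground truth: exhaustive depth-first
enumeration of every loopless path, sorted under the same tie order and the
same left-to-right cost arithmetic, guarded to 12 network nodes because the
count grows exponentially. The validation suite checks, on 200 seeded
instances of 4–8 nodes across densities 0.2/0.4/0.6 and all three weight
modes, that `yen_ksp()` returns *exactly* the oracle prefix for every
requested *k*, and that the consecutive-cost gap guarantee holds; a
2,000-node, 20,000-edge run at $k = 1000$ exercises the engine at scale.
These sizes keep the whole suite comfortably fast while covering the
regimes (sparse/dense, weighted/unweighted, tied/untied costs) where
k-shortest-path implementations typically fail.

## Design choices worth knowing about

* **Duplicate edges keep the maximum weight.** The loader cannot know the
  eventual weight mode, and under probability semantics the maximum is the
  strongest evidence; the collision is logged so users can pre-aggregate
  differently.
* **Self-loops are dropped at load time** — a loopless path can never use
  one.
* **SIF input is unweighted**; the relation column is discarded.
* **Endpoint-edge removal happens at query-graph construction** (the edges
  are simply not added) rather than through the hidden-element masks, which
  stay dedicated to Yen's spur machinery.
* **Sources and targets may overlap** without `targets_are_sources`; the
  two removal rules compose independently (in-edges removed because the
  node is a source, out-edges because it is a target).
* **Invalid `k` or penalty fall back to defaults** (`k = 200`; penalty 1 or
  0 by mode) with a warning rather than aborting, mirroring how an
  interactive tool would recover.

## Limitations

* Edge weights are taken as given; estimating them (e.g. Bayesian evidence
  weighting of an interactome) is out of scope.
* Paths with loops, and algorithms that rank non-simple paths (Eppstein),
  are out of scope; the loopless restriction is what makes the result a
  readable pathway.
* The engine is single-threaded, pure R; it is comfortable at
  interactome-like edge counts for k in the thousands, but very large k on
  very large networks is better served by compiled implementations.
* The brute-force oracle is for testing only and refuses networks with more
  than 12 nodes.
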