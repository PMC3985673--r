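---
title: "Constructing module maps from paired biological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing module maps from paired biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmapr)
```

## The model

Many questions about cellular organisation involve two complementary
relations over the same genes: one network `H` in which functional modules
are densely connected (protein--protein interactions, consistent
co-expression), and a second network `G` whose edges are informative about
relations *between* modules (genetic interactions, differential
co-expression).  A *module map* summarises both at once: a collection of
disjoint modules `M1, ..., Mp`, each a heavy subgraph of `H`, joined by
links that represent statistically supported inter-module connectivity in
`G`.  Every module of a finished map participates in at least one link;
genes that belong to no linked module stay out of the map.

Both networks are treated as signed symmetric relations.  In unweighted
mode an edge carries weight +1 and a non-edge -1; weighted mode stores a
real signed weight for every pair.  The objective is the **global score**

    score(F) = sum_i  W_H(M_i)  +  sum_{(U,V) in L}  W_G(U, V)

where `W_H(M)` sums the signed H-weights inside module `M` and `W_G(U,V)`
sums the signed G-weights across a linked pair.  The +1/-1 convention makes
density explicit: a module is worth having only when its internal edges
outnumber its internal non-edges, and likewise for links.  Links are not
chosen to maximise the score; they are *determined* by a significance test,
and can legitimately carry negative weight on sparse graphs (a pair can be
much more connected than chance while still below half density; the toy
worked example in the README shows exactly that).

## Link significance

Whether two node sets are linked is decided from per-node tests combined
into one p-value:

* **Hypergeometric + Fisher** (default, both modes): for each node `x` of
  either set, the number of `G'`-edges (unweighted `G`, or weighted `G`
  thresholded at weight > 0) from `x` into the opposite set is tested
  against the hypergeometric null with population "all nodes but `x`",
  successes "neighbours of `x`" and sample "the opposite set"; the upper
  tail is used, so the test is one-sided for enrichment.  All per-node
  p-values combine by Fisher's method.
* **Wilcoxon + Stouffer** (weighted alternative): per node, the weights
  into the opposite set are rank-compared with the weights into the rest
  of the network (one-sided, greater); the per-node p-values combine by
  Stouffer's method.  Exact tails are used for small untied samples,
  mid-ranks with a tie-corrected normal approximation otherwise, and a
  completely tied comparison returns 1 (it carries no evidence).

A pair with combined `p <= alpha` is *linked*; a pair whose p-value ever
reaches `beta` is *anti-linked* and is never tested again — merged sets
inherit anti-links from either parent.  Defaults are `alpha = 0.005`
(the value used for the yeast analyses) and `beta = 0.2`.  Per-node
p-values are floored at 1e-300 before log/quantile transforms.  The number
of combined tests performed during improvement is recorded so that
finalization can apply a Bonferroni bar (`0.05 / n_tests`), the option used
for the small DNA-damage networks.

## Initiators

Four first-phase algorithms produce disjoint seed sets (and, for the
pair-based ones, seed links):

* `mbcDicerInit()` — enumerate all maximal non-induced bicliques of `G'`
  (exhaustively, via Close-by-One over the Galois closure of the adjacency
  relation, in compiled code), then clean each side against `H`.  Cleaning
  iteratively removes the worst member whose summed signed H-weight to the
  rest of its side is non-positive.  One subtlety matters: around a map
  hub the maximal biclique's opposite side is the *union* of all the hub's
  partner modules, so the cleaning fixpoint is applied iteratively — core
  extracted, residue re-cleaned — until nothing of the minimum size
  remains; otherwise every partner but the strongest would be lost with no
  way back.  Component pairs are ranked by internal H score and accepted
  greedily, nodes first-come; a stripped side survives while it still has
  `minSize` nodes.
* `dicerKInit()` — seed one linked pair at a time from the heaviest unused
  positive G edge, expand each side greedily by the node with the best
  summed H-to-own-side plus G-to-opposite-side gain while that gain is
  strictly positive, clean both sides with the same fixpoint, and keep
  pairs with both sides of size at least `k` (`k = 5` by default, the
  value selected in the original comparison).  Greedy mining over
  thousands of seed edges is a massive implicit multiple test and readily
  assembles quasi-structures from pure noise, so accepted pairs must beat
  an empirically calibrated significance bar: the same scan is run on `H`
  paired with label permutations of `G` (three by default) and the real
  pair must be more significant than anything the null scans achieved.
  This mirrors the shuffled-label calibration used for differential
  co-expression scores.
* `hclustInit()` — average-linkage clustering of `H` on the distance
  `w_max - w`, cut at the zero-affinity height, oversized clusters split
  recursively.  No seed links.
* `greedyInit()` — repeated greedy module growth from the heaviest unused
  H edge.  No seed links.

## Improvers

The **global improver** (`globalImprove()`) starts from the seed sets plus
all uncovered nodes as singletons and greedily merges two modules or a
module and a single gene whenever the merge increases the global score and
the merged module's links (re-tested against every other module, with
anti-link inheritance) pass the significance threshold.  Merge gains are
exact score differences, so the trajectory of global scores is
non-decreasing by construction.  With `batch = TRUE` (default) an
iteration executes a maximal set of non-interacting positive-gain merges
in descending gain order; a proposal that conflicts with a better-ranked
one defers its members to the next iteration, which keeps batched results
equal to sequential ones on all instances we test while roughly halving
the iteration count.  Singleton--singleton merges are excluded (a pair of
genes cannot meet the minimum module size by itself), and candidate pairs
must share at least one positive H or G' pair unless widened explicitly.

The **local improver** (`localImprove()`) operates link by link: it adds
the single unassigned node with the best positive summed contribution to
either side of a link, and merges the two non-shared sets of two links
sharing a module when the combined pair score improves.  It cannot create
modules absent from the initial solution — the structural weakness that
motivates the global approach.

`finalizeMap()` drops undersized sets, applies the link threshold (raw
`alpha` or the Bonferroni bar), and removes modules left without links,
iterating until the every-module-linked invariant holds.

## The simulator

`simulateMap()` generates matched `H`/`G` pairs with known truth: planted
modules are cliques in `H*`, arranged on a uniformly random labelled tree
(Prüfer construction) whose edges become complete bipartite subgraphs in
`G*`; decoy cliques (in `H*` only) and decoy bicliques (in `G*` only)
stress specificity; all planted sets are pairwise disjoint with sizes
uniform on 10–20.  Noise is either independent pair flips with probability
`P` (unweighted) or Gaussian weights `N(+1, sigma)` / `N(-1, sigma)` on
planted / background pairs (weighted).  The default configuration — 500
nodes, 6 modules, 2 + 2 decoys — is the reference simulation condition;
the larger published condition (1000 nodes, 10 modules, 5 decoys) is
available by configuration, but its biclique enumeration at `P = 0.15`
exceeds the default result and work caps, so comparative experiments here
use the 500-node condition.  The five-decoy split for 1000-node
configurations is not dictated by the source description; we default to
3 cliques + 2 bicliques, configurable.

What the simulator does *not* emulate: degree-corrected or scale-free
backgrounds, overlapping modules, and weight distributions with heavy
tails.  Recovery results on these instances therefore speak to the
algorithmic behaviour under the stated planted model, not to performance
on any particular real interactome.

```{r quick-example}
sim <- simulateMap(simConfig(nNodes = 200, nModules = 4,
                             nCliqueDecoys = 1, nBicliqueDecoys = 1,
                             flipP = 0.1, seed = 7))
res <- runBuild(sim$H, sim$G, runConfig(seed = 7))
res$stats
pairJaccard(modules(res$map), slot(sim$truth, "modules"))
```

## Evaluation

`pairJaccard()` scores a recovered module collection against planted truth
as the Jaccard coefficient of co-membership node *pairs*.  This variant is
invariant to module labels and robust to module-count mismatch; it is the
metric used by every recovery number this package reports.  (The source
comparison does not pin down its exact Jaccard variant; a best-match
average would ignore spurious extra modules, which pair-Jaccard correctly
penalises.)  `linkVsNonlinkTest()` implements held-out map validation —
rank-comparing the mean cross weights of linked versus unlinked module
pairs in an independent network — and `linkFoldChange()` compares each
link's positive cross-weight mass (negative pairs contribute zero,
floored at `eps = 1e-6`) with the best of `repeats` random same-size set
pairs, the "best random link" convention.

## Numerical and design notes

* All pair structures are dense matrices; at the package's design scale
  (hundreds to a few thousand nodes) this is faster and simpler than
  sparse bookkeeping.
* Determinism: every tie in greedy loops breaks lexicographically by node
  identifier; enumeration output is canonically ordered; all randomness
  flows from the single configuration seed, so identical configurations
  give byte-identical results.
* Biclique enumeration caps: `maxResults = 1e6` bicliques and a work
  budget of 5e7 enumeration-tree nodes; hitting either flags the output
  as truncated (with a warning) rather than failing.
* Merge gains are exact, never approximated; an upper bound on the
  attainable gain prunes module-singleton candidates before the expensive
  link re-tests, without changing any accepted merge.
* Problem sizes used by the test suite and the acceptance script: the
  reference 500-node condition for recovery comparisons with five
  replicate seeds, 120–200-node instances for improver property checks
  (20 seeds), and 500 null draws for test calibration.  These sizes give
  stable means while keeping a full run in minutes on one core.
* Degenerate inputs: empty maps are valid outputs (finalization warns);
  a completely tied rank comparison returns p = 1; duplicate edge rows
  collapse (last weight wins, warning) and self-loops are dropped.

## Known limitations

* The improvement moves are additions and merges only; there is no module
  splitting and no restart mechanism, so a bad early merge cannot be
  undone.  This matches the two-phase design the package implements.
* Pair-based seeding consumes partner modules: a tree-leaf module whose
  only partner is already claimed cannot be re-seeded, which is why local
  improvement does not reach perfect recovery even on noiseless data.
  The biclique initiator with the global improver does not share this
  weakness and recovers noiseless planted maps exactly.
* With our exact merge gains and conservative batching, the global
  improver is never observed to *degrade* a pair-seeded start; published
  comparisons of the original implementations report the local improver
  clearly ahead of the global one for those starts.  Our local and global
  results from pair-based seeds are statistically indistinguishable
  instead; the gap presumably lies in unpublished details of the original
  simultaneous-merge scheme.
* The hypergeometric per-node test is discrete and therefore
  conservative under the null; calibration checks bound the false link
  rate at `alpha` from above, not tightly around it.
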