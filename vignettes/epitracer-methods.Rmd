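---
title: "Tracing epicenters in condition-specific networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing epicenters in condition-specific networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitracer)
```

## The model

A perturbation in a cell — overexpression of a regulator, knockdown of a
transcription factor — propagates along physical and regulatory
interactions. This package treats the interaction network as a directed
graph and the two expression profiles (control, perturbed) as per-node
abundance estimates, and asks: *from which nodes do highly active paths
spread out in one condition only?*

The key modelling assumptions are:

1. **Expression approximates abundance.** The normalized signal intensity
   of a gene, on the linear scale, is taken as the weight of the
   corresponding node. This is a deliberate simplification (it ignores
   translation and degradation rates) but it is what makes large networks
   tractable with routine data.
2. **Mass-action activity.** The activity of an interaction is taken
   proportional to the abundances of its participants, so the cost of a
   directed edge is `1/sqrt(w_u * w_v)` — the inverse geometric mean.
   Minimum-cost paths under this weighting are maximum-activity paths, and
   Dijkstra's algorithm applies because all costs are strictly positive.
   Path cost is the plain sum of edge costs.
3. **Only condition-specific activity is informative.** Paths retained in
   both conditions with the *identical node sequence* describe
   housekeeping flux; they are discarded from both sides. Path identity is
   deliberately strict (the exact ordered sequence): two paths that share
   every edge but one are evidence of re-wiring, not redundancy.
4. **An epicenter needs activity AND spread.** Ripple centrality is the
   product of normalized outward closeness and normalized outward
   reachability, both computed on the condition-specific highest-activity
   network (CSHAN). A node with very active paths to a handful of targets
   scores low on reach; a node that touches everything through weak paths
   scores low on closeness; only the combination marks an epicenter.

Closeness is directional by construction: it sums shortest-path costs
*from* the node outward, because influence flows along edge direction.

The analysis direction matters. Overexpression-type perturbations are best
read from the perturbed CSHAN; for a knockdown, the control CSHAN shows
the regulators that lost influence. `epitracer(..., analyze = "both")`
ranks both. Note that an epicenter is the origin of condition-specific
activity, which is not necessarily the causal source of the perturbation —
if the perturbed gene stays lowly expressed in both conditions it cannot
appear in any highest-activity path, and only its active neighbors will be
flagged.

## Normalization of the two factors

Outward reachability is normalized by `N - 1`, the maximum possible
number of reachable nodes. For closeness, the raw reciprocal sum
`1/sum(sigma)` is available (`closeness_out(..., normalized = FALSE)`),
but it is not usable directly as a ranking factor on directed graphs where
most nodes reach only part of the network: a node with a single very cheap
edge has an enormous reciprocal sum, and multiplying by the reachability
factor does not reliably undo that. The normalized score therefore uses
the standard Wasserman–Faust correction for partially reachable digraphs —
the reciprocal of the *mean* cost to the `r` nodes actually reached,
scaled by the reached fraction `r/(N-1)` — which is what the common
network libraries compute for directed closeness, and is then divided by
its maximum so both factors live in [0, 1]. The final max-scaling is a
single global constant, so it never changes an ordering; the
Wasserman–Faust correction does, and it is exactly what restores the
intended ordering (wide, active sources above one-lucky-edge nodes) on
heavy-tailed weight distributions. Absolute ripple values are therefore
implementation-defined; ranks are the meaningful output.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `percentile` | 0.1 | Percentage of candidate paths (ascending cost) retained per condition. Dimensionless. A conservative choice: retaining 0.2 roughly doubles the path count, diluting specificity. With N paths, `k = ceiling(q/100 * N)` and the realized cutoff is the k-th smallest cost; boundary ties are all kept. |
| `top_k` | 10 | Rank cutoff for the epicenter lists. Whole tie groups are kept, so a list may exceed `top_k` genes. |
| `deg_cutoff` | 1.5 | Fold-change cutoff for the differential-expression annotation attached to a fit. |
| `fc_cutoff` (influence zone) | 2.0 | Symmetric dysregulation cutoff for zone summaries: significant iff `fc >= c` or `fc <= 1/c`. |
| `hops` | 2 | Influence-zone radius, in unweighted hops, up- and downstream. |
| `max_frac` (sensitivity) | 0.05 | Upper bound of the uniform multiplicative noise, i.e. up to 5% per gene, mimicking detector variability. |
| `tie_tol` | 1e-9 (relative) | Scores closer than this share a rank. Exact float equality is too brittle; genuinely tied structures (symmetric positions) produce scores equal to rounding error. |

Intensities must be linear-scale and strictly positive; the reader's
`unlog2` switch converts log2 input, and non-positive values are rejected
by default (or floored to `min(positive) * 1e-3` on request, keeping
costs finite without letting a zero dominate the geometry).

## Numerical and procedural choices

* **Deterministic shortest paths.** Vertices are indexed in lexicographic
  name order; the compiled Dijkstra kernel breaks heap ties by smaller
  index and replaces a tentative distance only when strictly smaller.
  Among co-optimal paths this keeps one canonical representative, the same
  on every run and platform — required for the exact-sequence path algebra
  downstream and for regression testing. One path is kept per ordered
  pair.
* **"At least 2 edges."** Single-edge paths are excluded before the
  percentile ranking: a direct interaction carries no ripple information.
* **Streaming all-pairs stage.** The extractor never materializes all
  O(V²) paths: a first sweep collects only path costs, the percentile
  cutoff is computed, and a second sweep reconstructs the few paths at or
  below it. Memory is O(V) per source plus the output.
* **Within-list ranks.** The scored nodes are first split by membership
  (absent from the other CSHAN = specific; present in both = global) and
  competition ranks are assigned within each list, then truncated at
  `top_k` keeping tie groups. Ranks therefore answer "k-th best specific
  epicenter", which is how the lists are read.
* **Closeness on the CSHAN.** Both ripple factors are computed on the
  CSHAN with its own inherited edge costs, not on the full network: the
  ranking is meant to describe the condition-specific active subnetwork.
* **Degenerate inputs.** An empty CSHAN aborts ranking with a hint to
  raise the percentile; a sink node has closeness and reachability 0; a
  graph whose only "components" are single nodes has no meaningful
  strongly connected core, so the LSCC report flags no members.
* **Influence zones.** Hop counts are unweighted BFS distances computed
  with lexicographically ordered neighbor expansion, so the reported
  intermediate nodes are deterministic. A gene both upstream and
  downstream within range gets one row per direction. When the zone is
  computed on a CSHAN, dysregulated genes within range in the full
  condition network can be pulled in (`augment_from_full`, default
  `"down"`), with their hop counts taken from the full network — the zone
  table mixes graphs in that case, which is intentional and flagged by the
  `Which_network` column.
* **Sensitivity protocol.** Each repetition perturbs *both* condition
  profiles independently — detector noise affects every array — by
  `(1 + u)` or `(1 - u)`, `u ~ U(0, max_frac)` per gene. Draws come from a
  counter-based hash stream keyed by (seed, repetition, direction,
  condition, gene), so results do not depend on gene order or evaluation
  order and repetitions can be computed independently; the master seed
  makes the whole report reproducible bit for bit.

## The synthetic generator

`generate_case()` builds the validation fixture: a directed scale-free
graph (preferential attachment, each edge's orientation randomized —
interaction networks are heavy-tailed, and epicenter detection interacts
with hub structure), log-normal control intensities (`meanlog = log(100)`,
`sdlog = 1`: linear-scale values centered near 100 with about a decade of
spread, as after standard array normalization), and a planted
perturbation: one well-connected node (largest d-hop out-neighborhood
among nodes covering at least 10% of the graph) is overexpressed by a
factor `f = 8`, and genes `h <= d = 2` hops downstream receive expected
ratio `1 + (f - 1) * alpha^h` (`alpha = 0.5`), a 35% fraction of them
inverted to downregulation — a local source with mixed-sign downstream
effects, as seen after overexpressing a regulator. All genes except the
planted node get multiplicative log-normal noise (`noise_sd = 0.1`); the
planted node's ratio is exactly `f`. Its control baseline is fixed at the
10th intensity percentile: the emulated scenario is the re-expression of a
gene that is silenced or deleted in the control cells, and a baseline left
to chance would as often as not make the planted hub a legitimate member
of the *control* active network, which is a different experiment.

What the fixture does **not** emulate: transcriptional regulation dynamics,
correlated replicate noise, probe-level artifacts, or biased false edges
in the network. Passing the recovery tests therefore shows that the
pipeline's machinery is correct and that the method recovers a planted
source under idealized conditions; it does not certify performance on real
arrays.

## Validation and problem sizes

The test suite checks, among others: exact agreement of the all-pairs
stage with exhaustive simple-path enumeration and of ripple vectors with
an independent relaxation-matrix/transitive-closure oracle (200 random
graphs of up to 8 nodes); end-to-end invariance of paths, CSHANs and
rankings under global intensity rescaling by 0.01–37 (all costs scale
together, and every normalization is scale-free); planted-epicenter
recovery on the default 300-node fixture over the seed panel 1–20 (mean
specific-list rank ≤ 3, rank 1 at seed 42); stability of the planted node
in the top 10 across 40 noisy repetitions at 5% noise; BFS-exact hop
counts in influence zones; and the conservation identity
`|unique_A| + |unique_B| + 2|common| = |A| + |B|`. These sizes keep the
whole suite under a minute while exercising every code path at scales
where brute force is still exact.

## Known limitations

* **Small-fixture granularity.** At 300 nodes the 0.1 percentile retains
  only ~55 paths per condition, so the CSHANs are small and recovery has
  real variance across generator seeds: in an unlucky realization the
  planted node's paths can miss the perturbed cutoff, or a single top
  control path can touch the planted hub and re-classify it as a global
  (re-wired) epicenter. The seed-1..20 panel satisfies the mean-rank bound;
  other windows occasionally do not. On networks of realistic size
  (thousands of nodes, tens of thousands of retained paths) this
  granularity effect shrinks.
* **Epicenter ≠ cause.** The method ranks origins of condition-specific
  activity; upstream "supporter" nodes of the true source can legitimately
  outrank it.
* **One value per gene per condition.** Replicates are collapsed by the
  arithmetic mean before analysis; replicate-level uncertainty is not
  propagated (the sensitivity protocol is the intended substitute).
* **Percentile semantics.** `q` is a percentage of the path *count*; the
  realized cost cutoff is data-dependent and reported in the `hap_set`.
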