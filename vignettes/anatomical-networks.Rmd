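---
title: "Anatomical network analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbnet)
```

## The model

An anatomical network codes the physical organization of a body part as an
undirected, simple, unweighted graph. Nodes are anatomical parts — bones and
cartilages, or muscles, or both — and an edge records a physical contact:
an articulation between two bones, a tendinous fusion between two muscles,
or a muscle-bone attachment. Contacts are binary; repeated or graded
contacts collapse to a single edge. From one musculoskeletal network the
two tissue layers are recovered as induced subgraphs
(`extract_subsystem()`), so the skeletal, muscular and musculoskeletal
views of a limb are always mutually consistent.

The analysis asks three questions of such a graph:

1. **How is it organized globally?** Five descriptors: density
   `D = 2K / (N(N-1))`; mean clustering `C`; mean shortest path length `L`;
   the diameter; and degree heterogeneity `H = sigma_K / mu_K`.
2. **Is the organization non-random?** Small-worldness is judged against
   uniform random graphs with the same `N` and `K`; hierarchy by power-law
   fits of the degree profile `P(k)` and the clustering-by-degree profile
   `C(k)`.
3. **What are its connectivity modules?** Groups of parts with more
   contacts among themselves than with the rest, found by a random-walk
   agglomeration whose cut level is selected by Newman modularity `Q`.

Modules matter because they formalize morphological *integration* (fewer,
larger modules) versus *parcellation* (more, smaller modules), and because
partitions of different limbs, developmental stages or pathological
conditions can be compared quantitatively.

## Numerical definitions and edge cases

Several conventions differ between toolkits, so the ones used here are
stated explicitly.

* **Clustering.** The local coefficient of node *i* is
  `2 tau_i / (k_i (k_i - 1))`; nodes of degree < 2 contribute 0, and the
  mean is over all `N` nodes. This keeps `C` well defined for the muscular
  networks, which are mostly isolated muscles.
* **Path length.** `L` and the diameter average and maximize over
  unordered pairs joined by some path; unreachable pairs are excluded
  rather than penalized. A network with no edges has no paths at all and
  reports `L = NA`. The same convention applies inside the random
  ensembles, whose sparse replicates are often disconnected.
* **Heterogeneity.** `H` is the coefficient of variation of the degree
  sequence with the population standard deviation, so `H = 0` exactly when
  all degrees are equal — including the all-isolated case.
* **Modularity.** `Q = (1/2K) sum_ij (A_ij - k_i k_j / 2K) delta(m_i, m_j)`
  over ordered pairs, diagonal included; an edgeless network gets `Q = 0`
  with a warning. Isolated nodes are singleton modules, which is what makes
  module counts of near-empty muscular networks meaningful (each
  unconnected muscle is its own one-muscle module).

## The walktrap agglomeration

Module detection implements the short-random-walk agglomeration with walks
of length `t = 3` (the `steps` argument). For each connected component the
`t`-step transition matrix is computed and communities are merged bottom-up,
always the adjacent pair minimizing the Ward-style variation `delta sigma`;
distances after a merge follow the Lance-Williams-style update where both
distances are known and are recomputed from the community probability
vectors otherwise (the two routes are algebraically identical).

Two details deserve emphasis:

* **The walk is lazy.** Every node carries a unit self-loop during the
  walk, matching the published implementation of the algorithm; without the
  self-loops the merge order — and frequently the final partition — is
  different. With the lazy walk, this implementation reproduces the module
  counts of the independent igraph implementation on 96% of random graphs
  with up to 60 nodes; the residual differences are tie-resolution
  artifacts with essentially equal `Q`.
* **Ties are deterministic.** Equal `delta sigma` values are resolved
  towards the merge with the lowest (smaller, then larger) community index,
  so dendrograms are reproducible across runs and platforms.

The partition reported is the cut of the dendrogram maximizing `Q`.
Because `Q` is additive over connected components, each component's cut
level is selected independently; ties go to fewer modules. Walktrap is a
heuristic: on graphs small enough to enumerate every set partition its best
cut is usually at, and occasionally up to a few hundredths of `Q` below,
the global optimum — the same gap the reference implementation shows.

## Null models

* **Random equivalent networks** are uniform simple graphs with the same
  `N` and `K` ("the same nodes, re-connected at random"), not
  degree-preserving rewirings. The conventional ensemble size is 10,000;
  the test suite and the acceptance script use 1,000, which leaves the
  ensemble means' standard errors far below the decision margins involved.
* **Small-world verdict:** `(C/C_rand) / (L/L_rand) >= 0.012 * N^1.11`.
  The size-corrected threshold makes verdicts comparable across networks
  from a few dozen to a hundred nodes. If the null ensemble has zero mean
  clustering, or the network has no paths, the verdict is explicitly "not
  assessable" rather than a number.
* **Hierarchy verdict:** least-squares fits of `log P(k)` and `log C(k)`
  on `log k` over the strictly positive profile points. Both fits must
  reach `r2_min` (default 0.7, configurable and recorded in the output)
  and the `C(k)` slope must be negative. The 0.7 default is a declared
  choice — the criterion is surfaced in every result object precisely
  because reasonable thresholds differ, and hierarchy booleans should be
  read with that in mind. Profiles with fewer than three usable points are
  "not assessable".
* **Reproducibility.** Each ensemble draws all replicates from a single
  RNG stream seeded once from the master seed, so summaries are
  reproducible bit-for-bit; the caller's RNG state is restored afterwards.

## Comparing partitions

Two measures quantify agreement between partitions:

* The **co-classification ratio**: the number of elements placed in
  corresponding modules in both networks, divided by the number of elements
  common to both. "Corresponding" is decided by the one-to-one module
  matching that maximizes total overlap (a maximum-weight bipartite
  matching on the contingency table), which is deterministic and symmetric.
* **Normalized mutual information**, `2 I(A;B) / (H(A) + H(B))`, oriented
  so identical partitions score 1; the degenerate case of two one-group
  partitions is defined as identical. `similarity_percent` is `100 * NMI`.

Upper-limb versus lower-limb comparisons need an explicit serial
correspondence between labels (`serial_homology_map()`), shipped as an
editable two-column table covering the widely accepted bone
correspondences; nothing is inferred from string similarity. Proximal
versus distal organization is compared through `proximal_distal_params()`:
networks are split by region (girdle and stylopod structures, and muscles
attached to them, are proximal by default — also an editable table), and
the parameter vectors are scored by the mean absolute relative difference
over the size-free descriptors `D`, `C`, `L`, `H`. This dissimilarity score
is a declared choice; any metric monotone in coordinate-wise disagreement
would order the comparisons similarly.

## What the synthetic generators emulate — and what they do not

`limb_like_network()` reproduces the topological regime of real limb
networks: a connected, sparse, tree-like skeleton (girdle block, stylopod,
two-bone zeugopod, wrist/ankle block, serial digit chains; density below
0.1 at the default 33 bones), a near-empty muscular layer (57 muscles,
a handful of fusion contacts), and a musculoskeletal layer whose triangles
come from muscles spanning joints — attaching to two bones that articulate
with each other — which is exactly how real muscle attachments create
clustering. Muscles sample an origin and an insertion, occasionally a third
attachment, so musculoskeletal modules mix bones with the muscles that
move them.

`planted_partition_graph()` provides ground truth for module recovery:
Bernoulli edges with within-module probability `p_in` and between-module
probability `p_out`. At the benchmark conditions (4 modules of 20,
`p_in = 0.5`, `p_out = 0.02`) the walktrap pipeline recovers the planted
partition essentially perfectly, and recovery degrades monotonically as
`p_out/p_in` grows.

What the generators do *not* emulate: real anatomical label semantics,
left-right asymmetries, the specific carpal/tarsal articulation patterns,
or any developmental process. Passing tests on synthetic data therefore
demonstrates that the pipeline measures what it claims on networks with the
right statistical structure — not that any particular anatomical claim
about real limbs is reproduced. Reproducing published limb values requires
the deposited adjacency matrices, which must be obtained separately and
read with `read_limb_deposit()`.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated data:
brute-force oracle checks on 100 random graphs of up to 12 nodes and 200
random graph-partition pairs of up to 10 nodes; null-model behaviour on
100-node graphs with 1,000-replicate ensembles; module recovery on 80-node
planted partitions over 20 seeds; and cross-validation against the
independent walktrap implementation on 50 random graphs of up to 60 nodes.
These sizes were chosen to exercise every code path at the scale of real
limb networks (34-92 nodes) while keeping a full run in the order of
seconds to minutes.

## Known limitations

* Networks are binary and undirected by design; weighted contacts
  (attachment areas, articulation sizes) are out of scope.
* Walktrap with max-`Q` selection inherits the resolution behaviour of
  modularity: very small modules attached to large ones can be absorbed.
* Hierarchy verdicts from simple log-log fits are sensitive to the few
  distinct degrees present in small networks; they are reported with their
  criterion and should not be over-read.
* The default region and serial-correspondence tables are coarse,
  documented defaults meant to be edited by someone who knows the anatomy
  of the system under study.

## A worked example

```{r example, eval = FALSE}
library(limbnet)

limb <- limb_like_network(seed = 7)
fit <- anna(limb, steps = 3, n_random = 1000, seed = 7)
fit          # parameters, verdicts, module count
summary(fit) # module membership

systems <- list(
  musculoskeletal = limb,
  skeletal = extract_subsystem(limb, "skeletal"),
  muscular = extract_subsystem(limb, "muscular"))
report <- analyze_networks(systems, n_random = 1000, seed = 7)
report$table
```
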