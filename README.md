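# limbnet

Anatomical network analysis (AnNA) of limb musculoskeletal systems in R.

Morphologists ask how the parts of a body region — bones, cartilages,
muscles — are organized into modules (groups of tightly inter-connected
parts) while remaining integrated into a working whole, and how that
organization differs between body parts, developmental stages, and normal
versus pathological phenotypes. Classical morphometrics struggles when the
structures being compared have different architectures or mixed tissue
types. AnNA sidesteps this by coding the *physical contacts* among parts as
a graph — nodes are bones/cartilages and muscles, edges are articulations,
tendinous fusions and attachments — and comparing topology instead of
shape. `limbnet` is for comparative anatomists, evo-devo researchers and
network scientists who want that pipeline as ordinary R functions with
reproducible, seeded nulls.

## What it computes

For a binary symmetric adjacency matrix with `N` parts and `K` contacts:

* **Global descriptors** — density `D = 2K/(N(N−1))`; mean clustering
  coefficient `C` (local coefficient `2τᵢ/(kᵢ(kᵢ−1))`, degree-<2 nodes
  counting 0, averaged over all nodes); mean shortest path length `L` and
  diameter over reachable pairs; degree heterogeneity `H = σ_K/μ_K`.
* **Small-world test** — `C` and `L` are compared with the means of an
  ensemble of uniform random graphs on the same `N` and `K`; the network is
  small-world when `(C/C_rand)/(L/L_rand) ≥ 0.012·N^1.11`.
* **Hierarchy test** — power-law fits of the degree profile `P(k) = n_k/N`
  and the clustering profile `C(k)`; hierarchical organization requires
  good fits (R² ≥ 0.7 by default, configurable) with clustering declining
  in degree.
* **Connectivity modules** — a from-scratch 3-step random-walk (walktrap)
  agglomeration builds a merge dendrogram per connected component; the
  partition maximizing Newman modularity
  `Q = (1/2K) Σᵢⱼ (Aᵢⱼ − kᵢkⱼ/2K) δ(mᵢ, mⱼ)` is returned. Isolated parts
  are singleton modules.
* **Partition comparison** — the co-classification similarity ratio
  (matched-module overlap over elements in common, with optimal one-to-one
  module matching) and normalized mutual information (1 = identical);
  proximal-vs-distal parameter comparisons between limbs.
* **Synthetic generators** — limb-like musculoskeletal networks and
  planted-partition benchmark graphs, so the whole pipeline is testable
  without any data download.

## A worked example

```r
library(limbnet)

limb <- limb_like_network(seed = 7)   # synthetic 90-part musculoskeletal limb
fit  <- anna(limb, steps = 3, n_random = 1000, seed = 7)
fit
#> Anatomical network analysis
#> <anatomical_network> musculoskeletal system: 90 nodes, 173 edges
#>   classes: bone_cartilage=33, muscle=57
#>   regions: distal=80, proximal=10
#> N=90 K=173 D=0.043 C=0.354 L=3.588 diameter=7 H=0.636
#>   modules: 11 (Q = 0.5525)
#>   small-world: yes (swi 8.53 >= 1.77)
#>   hierarchical: no
```

The five descriptors summarize the limb's topology: a sparse network
(4.3% of possible contacts) with strong triangle clustering (C = 0.35,
created by muscles attaching across joints) and short paths (L = 3.6).
Its clustering-to-path-length ratio against 1,000 random equivalent
networks (swi = 8.53) clears the size-corrected threshold (1.77), so the
organization is small-world: its modules are unlikely to be noise. The
max-modularity walktrap cut finds 11 modules at Q = 0.55 — a strongly
modular partition mixing bones with the muscles that move them.

Analysing the three tissue systems together:

```r
systems <- list(musculoskeletal = limb,
                skeletal = extract_subsystem(limb, "skeletal"),
                muscular = extract_subsystem(limb, "muscular"))
report <- analyze_networks(systems, n_random = 1000, seed = 7)
report$table
#>          network  N   K        D       C     L Diameter      H n_modules      Q    swi small_world hierarchical
#>  musculoskeletal 90 173 0.043196 0.35374 3.588        7 0.6359        11 0.5525 8.5306        TRUE        FALSE
#>         skeletal 33  37 0.070076 0.04848 4.888       11 0.4256         8 0.6176 0.7592        TRUE        FALSE
#>         muscular 57   5 0.003133 0.00000 1.167        2 2.4166        52 0.7200     NA          NA           NA
```

The skeletal layer is tree-like (C ≈ 0.05) and splits into digit-chain and
girdle modules; the muscular layer is almost edgeless — each unconnected
muscle is its own module (52 modules from 57 muscles) — and too degenerate
for a small-world verdict (`NA`). `write_anna_report()` exports the table,
module memberships and dendrograms; `compare_reports()`,
`partition_similarity()` and `nmi_similarity()` quantify agreement between
limbs or against a priori functional/developmental groupings.

To analyse real limbs, read adjacency CSVs with `read_adjacency_csv()`
(node classes resolve through the bundled anatomical label table or a
sidecar file), or point `read_limb_deposit()` at a local copy of published
limb matrices.

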