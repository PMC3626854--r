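---
title: "Partial clustering for decoy selection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial clustering for decoy selection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsforest)
```

## The selection problem and the model's assumptions

Given `N` candidate structures (decoys) of a common length generated for one
protein target, the goal is to return the decoy closest to the unknown
native structure. The method rests on two assumptions:

* **Clustering hypothesis.** With a reasonably good sampler and energy
  function, decoys accumulate near the correct fold, so dense regions of
  the decoy set's metric space — not the single lowest-energy decoy — are
  where the best candidate lives.
* **Metric concentration.** Two similar decoys have similar distances to
  any third decoy. This holds for Cα RMSD (a metric) and approximately for
  non-metric similarity scores, and is what makes one-dimensional
  pivot-distance hashing locality sensitive.

The pipeline (`run_hs_forest()`) is: pivots → median-split hashing
functions → `T` randomized trees → per-tree candidates → consensus.
Density detection is *partial*: cluster membership is decided only for
decoys on paths that reach a cluster node, and the union of cluster nodes
need not cover the set. That is deliberate — the deliverable is a
representative, not a partition.

## Cluster nodes: balancing height and size

A tree node at height `h` (root = 0) holding `z` of the `Z` decoys is a
cluster node when

\[ h / H_{max} \ge \log z / \log Z . \]

Node size decays roughly geometrically with depth, so `log z / log Z` is
the size analogue of the height fraction; a node satisfying the inequality
is at least as deep (dense) as its size warrants. The ratio makes the rule
independent of the logarithm base; we use natural logs. Descent stops at
the first satisfying node on each path, so each root-to-leaf path holds at
most one cluster node and only a fraction of the tree is built.

Two properties anchor the rule:

* The median split keeps the larger bin at or below `2/3` of the node
  (equality only for a 3-element node), because the threshold is the
  sorted-row value at 0-based index `⌊N/2⌋` and the strict `<` test sends
  `⌊N/2⌋` members to bin 0. The constant behind that bound,
  `log(3/2) ≈ 0.40546` (the package tests pin this to the printed 5-decimal
  precision; it is a truncation of 0.4054651), makes `log z / log Z < 1`
  for every node below the root of a split tree.
* Consequently, when the *realized* tree height `H` is used in the rule
  (`build_tree(..., exact_height = TRUE)`), every tree with `H ≥ 1` has at
  least one cluster node: the deepest leaf satisfies the inequality, and
  the first satisfying node above it is marked instead if one exists. The
  test suite and `scripts/acceptance.R` verify this over hundreds of
  randomized trees on sets of 2 to 1000 decoys.

During construction the height bound `H_max` replaces the realized height
`H` (they coincide on large sets). The price of that approximation is that
a tree can, rarely, end every path in a degenerate split and produce no
cluster node; the run then fails with an `hsforest_empty_result` error
whose advice — reduce `h_max` — restores the guarantee. We observed this
only at very small `P`/`N` with tight single clusters (about 1 run in 40 at
`P = 10`, `N = 99`).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `P` | 40 | pivots | hashing functions available; drives the `P × N` distance matrix, the dominant cost. Useful range 20–60: too few pivots give coarse hashes, very many make the cluster rule harder to satisfy. |
| `T` | 30 | trees | consensus stability; performance saturates above ~15 trees. |
| `S` | 30 | clusters | largest cluster nodes ranked per tree; levels off above ~10. |
| `E` | 10 | decoys | lowest-energy reference decoys; weak influence. |
| `H_max` | `P/2` | levels | keeps tree depth below the pool size so different trees sample different hash subsets. |
| `metric` | `ca_rmsd` | Å | or `gdt_ts_distance` (unitless, in [0,1]); swapping the metric changes every stage consistently. |

The distance budget `P·N + T·S·E + C(T,2)` is enforced against a memoized
unique-pair counter (`distance_tracker()`); self-distances are free and
symmetric duplicates are never recharged, so the realized count is strictly
below the bound.

## Numerical choices and tie-breaks

* **Superposition.** Kabsch via SVD of the 3×3 cross-covariance with a
  determinant-sign correction, so reflections are never returned and
  collinear point sets still yield a minimizing transform. Tests verify it
  against an independent rotation-grid-plus-refinement search and against
  `bio3d`'s fitted RMSD.
* **GDT-TS.** The per-cutoff maximal coverage is approximated by seeding
  superpositions from the global fit and from all contiguous windows of
  lengths 3, 5 and `N/2`, each refined by re-superposing on the residues
  currently within the cutoff (≤ 10 iterations). On small cases this
  matches an exhaustive subset-seed oracle; an exhaustive search could in
  principle score marginally higher on adversarial inputs.
* **Median.** "The median" is realized as the lower-upper order statistic
  (0-based index `⌊N/2⌋`), which reproduces the 1|2 split of a 3-element
  node that the 2/3 balance bound is tight on.
* **Ties.** Distances equal to the threshold go to bin 1; representative
  and candidate ties go to the lowest decoy index; cluster-size ties keep
  discovery (depth-first, bin0-first) order — all so that a seed fully
  determines the result.
* **Degenerate splits** (every member on one side, e.g. duplicated
  structures): the node becomes a non-cluster leaf unless it already
  satisfies the cluster rule; an all-identical decoy set therefore raises
  `hsforest_empty_result` rather than recursing forever.
* **Energies.** The `E` lowest-energy decoys are a single global list
  (ascending energy, ties by index), not per-tree. Energy tables join
  decoys by filename stem. With no energies at all, the pivot-based
  consensus pseudo-energy (`consensus_energy()`, the pivot-matrix column
  sums) substitutes at zero extra cost; the pivots themselves serve as the
  reference structures.
* **Consensus.** Candidate multiplicity is kept: a decoy chosen by several
  trees contributes its votes' weight to every total, and duplicates
  contribute zero to their own total. Adding another copy of the current
  consensus can therefore never dethrone it.
* **Evaluation criteria.** Criterion-1 uses strict "farther than" with the
  full set size as denominator; Criterion-2 counts strict wins over the
  baseline. Ties favor neither method; the same convention is applied to
  every compared method, so comparisons are unaffected.

## The synthetic generator

`generate_decoy_set()` emulates the statistical shape of real decoy
collections: `K` clusters of chosen sizes whose centers are Gaussian
deformations of a self-avoiding random backbone (3.8 Å consecutive Cα
spacing, 80–150° pseudo-bond angles, ≥ 3 Å non-adjacent separation),
calibrated by bisection so each center's superposed RMSD to the native hits
its target (the scale–RMSD map has no closed form after fitting); members
scatter isotropically around their center; outliers sit 8–14 Å from the
native; and pseudo-energies are `slope · RMSD-to-native + noise`, with an
inverted mode that emulates an energy function favoring wrong folds. The
default spec places the dominant, tightest cluster 2.5 Å from the native,
which also guarantees the benchmark inclusion rule (at least one decoy
below 4 Å).

What the generator does *not* emulate: physically realistic backbones
(fragment-assembly geometry, secondary structure, side chains), non-Gaussian
cluster shapes, and the heavy-tailed energy errors of real force fields.
Passing tests therefore demonstrate the algorithmic properties — balance,
budget, consensus recovery of a dominant cluster, rescue of a corrupted
energy ranking — not performance on any real decoy collection.

## Problem sizes used by the tests

The suite exercises sets from 2 to roughly 20,000 decoys (the latter for the
sub-quadratic budget demonstration, at 20 residues and full `P = 40`,
`T = 30` defaults) and uses scaled parameters `P = 10`, `T = 5`, `S = 5`,
`E = 3` for repeated-seed studies on sets of one to two hundred decoys —
sizes at which a selection run takes well under a second, so 20-seed
averages over 20 sets remain cheap. Recovery assertions (consensus in the
dominant near-native cluster in ≥ 90% of seeds; clustering-guided
Criterion-1 at or above the energy-only baseline when 2 of 20 sets carry
inverted energies) are made at these scales.

## Known limitations

* The empty-result failure mode described above, inherent to the `H_max`
  approximation; the remedy is a smaller `h_max`.
* Selection quality degrades on decoy sets with no near-native decoys, and
  on very small sets there is little for partial clustering to exploit.
* GDT-TS mode costs far more per distance than RMSD mode (many seeded
  superpositions per pair) and is practical at moderate `N` or small `P`.
* Trees are built serially; the contract is a seed-deterministic serial
  order.
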