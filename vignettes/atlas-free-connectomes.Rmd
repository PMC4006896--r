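---
title: "Atlas-free structural connectomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-free structural connectomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion-MRI connectomics represents a brain as a network: patches of
cortical surface are the nodes, and white-matter connections reconstructed
as tractography streamlines are the edges. The usual way to define nodes —
registering every brain to a standardized anatomical atlas — assumes that
anatomy is comparable across subjects. It is not, in exactly the
populations where connectomics is most informative: neonates with immature
sulcation, infants, and brains reorganised by injury or surgery.

`connalign` implements the alternative: *no* anatomical registration at
any point. Nodes come from an equal-area partition of a reference sphere
scaled to each individual surface, and correspondence between subjects is
established afterwards, in the **network domain**, by reordering the nodes
of one adjacency matrix to match another. The package covers the whole
pipeline — dense connectome, parcellation, optimal node count, binary
N×N networks, normalised graph metrics, simulated-annealing alignment,
cohort reference and sum networks, and edge-wise group statistics — plus a
synthetic phantom generator that makes every stage testable without MRI
data.

## Pipeline and model assumptions

**1. Dense connectome.** Streamlines shorter than a minimum length are
removed first (`filter_by_length()`); short streamlines are dominated by
noise and the oversimplification of tensor modelling. Reference
thresholds: 5 mm for neonates, 10 mm for 6-month-old infants, 15 mm for
adults (the `min_streamline_length_mm` config field, default 15).
`build_dense_connectome()` then connects individual surface points: each
streamline endpoint is mapped to the nearest surface point within
`endpoint_radius_mm` (default 2 mm, about one voxel — the geometric
reading of "the streamline intersects the patch"). Only the two endpoints
are used, never interior passage, and streamlines whose endpoints map to
the same point are dropped (no self-loops). Both choices are documented
defaults rather than uniquely correct readings; the endpoint radius is a
config field.

**2. Parcellation.** `equal_area_partition(N)` divides the unit sphere
into N regions of *exactly* equal area by recursive zonal partitioning:
two polar caps of area 4π/N and latitudinal collars divided into equal
longitude cells, with every zone boundary placed so the enclosed cap area
is an exact multiple of 4π/N. The algorithm is deterministic, and
`partition_region_areas()` returns the per-region areas analytically (they
equal 4π/N to 1e-9; the test suite additionally verifies uniform
Monte-Carlo hit fractions). The region *centers* serve as node reference
points: `scale_to_surface()` maps them by the surface centroid plus
per-axis half-ranges (the simplest affine scheme matching an
ellipsoid-like brain; a PCA-aligned alternative could be swapped in behind
the same interface), and `assign_nodes()` labels every surface point with
its nearest reference point, ties to the lowest index. Nodes whose region
contains no surface points are *kept* as isolated nodes — detecting them
is precisely how the optimal N is found.

**3. Optimal N and the N×N network.** The only anatomical assumption the
framework retains is that no part of the brain is structurally isolated.
`find_optimal_n()` therefore returns the largest candidate N (default
candidates 10, 50, 90, 95, 100, 105, 110, 150, 300, 500, 1000, 3000) at
which every subject's N-node network forms a single connected component;
an explicit `NA` outcome means no candidate qualifies. `downscale()` sums
dense-connectome counts between node pairs and binarizes at a threshold of
one streamline. Streamline counts are retained as weights but drive
nothing downstream: binary analysis avoids the systematic biases of
streamline-count weighting (smaller brains yield fewer streamlines per
parcel, and weighted alignment is dominated by the uneven count
distribution).

**4. Metrics.** `global_metrics()` computes the average clustering
coefficient C (degree-<2 nodes contribute 0), characteristic path length
L (mean over all unordered pairs; defined only for connected input — a
disconnected network is an explicit error directing the caller to
`giant_component()`), and maximised modularity Q (best of 20 seeded
Louvain restarts; the maximiser is not prescribed by the method, Louvain
is this package's choice). Because all of these depend on edge count and
degree distribution, C and L are normalised by their means over an
ensemble of degree-preserving random networks: `Cr = C/C_rand`,
`Lr = L/L_rand`, and the small-world index `swi = Cr/Lr`. The
randomization is Maslov–Sneppen double-edge swapping with
*accepted-swap* semantics — `rewires_per_edge × |E|` accepted swaps per
network (reference values: each edge rewired 1000 times, ensemble of
100) — implemented in compiled code; an attempt budget returns inputs
that admit no swap (e.g. complete graphs) unchanged. If a randomized
network falls apart, its L is measured on its giant component. The
metrics vary systematically with N, so metric values are only comparable
at a common parcellation scale.

**5. Alignment.** `sa_align(reference, moving)` minimises
`sum(|reference − moving[p, p]|)` over permutations p by Metropolis
simulated annealing: transposition proposals, initial temperature
`cost₀/ln 2` (a cost-doubling move starts 50% acceptable), geometric
cooling per sweep of N proposals, stop at `iterations` sweeps or at
1e-4 of the initial temperature, best cost over `restarts` restarts
(reference protocol: 100 restarts, keep the lowest cost). Two starts are
deterministic — the identity (cohort scans with similar head positioning
are effectively pre-aligned) and the degree-rank matching permutation —
and the rest are random. Because the matrices are binary with fixed
margins, a lower cost is equivalent to a higher lower-triangle Pearson
correlation, so including the identity start guarantees
`r_after ≥ r_before`. The default cooling factor is 0.955: the schedule
must actually reach its 1e-4 temperature floor within the default
200-sweep budget (0.955²⁰⁰ ≈ 1e-4) for the chain to freeze; with slower
cooling the search stays hot for the whole run and recovery of planted
permutations fails. Good solutions are practical up to roughly 100 nodes,
which is one reason the optimal-N rule landing near 95 is convenient.
Similarity is always `pearson_lower_triangle()`: the N(N−1)/2 elements
under the diagonal (4950 for N = 100, 4465 for N = 95). `sa_align`
reports the r of the lowest-cost run, not an average over runs.

**6. Reference, sum network, statistics.** `pairwise_align_group()` fills
the directional S×S correlation matrix (row = reference);
`select_reference()` picks the subject with the highest mean off-diagonal
row value — the most *typical* network, so the template is not built on
the cohort's most deviant member. Row means (not column means) define
typicality because alignment is directional; the pairwise matrix is not
exactly symmetric and the package documents rather than hides that.
`sum_network()` adds the aligned binary matrices: entry = number of
subjects possessing the connection, a template in network space.
`edgewise_ttest()` + `fdr_correct()` give mass-univariate inference;
`nbs()` implements the four-step network-based statistic with corrected
p-values `(1 + #(null ≥ size))/(K + 1)` — never below `1/(K+1)` — with
component size measured in edges (the edge is the unit of inference;
`component_size = "nodes"` is available). Zero-variance edges, common for
binary data at small n, get t = 0 when group means agree and a signed
sentinel (±1e12) when they differ; the NBS permutation machinery is
unaffected by the sentinel's magnitude since only the threshold crossing
matters. The primary threshold is deliberately a required argument: no
principled default exists.

`rotation_analysis()` quantifies the error introduced by node
discretization: rotating the reference sphere ±10° about each axis (about
half a node at N = 95) shifts every node border, so a coherent bundle
that straddles a shifted border turns one binary connection into two.
The rotated networks are realigned to the 0° baseline (whose r is 1 by
construction); rotations that disconnect the network are flagged, since
alignment is then not properly defined.

## The phantom generator

The phantoms define the package's study conditions. `make_surface()`
samples points area-uniformly (rejection sampling) on an ellipsoid with
half-axes 60 × 80 × 50 mm by default — an adult-brain-scale stand-in for
the subcortical surface. `make_ground_truth_network()` draws a
planted-partition network (default 4 modules, p_in = 0.8, p_out = 0.05 —
strongly modular, as brain networks are); if the draw is disconnected a
ring through one node per component is added and flagged, and the repair
can be disabled to construct deliberately disconnected phantoms.
`synthesize_streamlines()` inverts the connectome builder: per ground-truth
edge it emits streamlines between (optionally jittered) surface points of
the two nodes, routed through a deep interior waypoint so every polyline
clears the 15 mm adult length threshold at brain scale. With zero jitter,
rebuild-and-downscale recovers the planted adjacency *exactly* — the
module's defining oracle. `make_cohort()` models within-group variability
as iid Bernoulli edge flips (so the Hamming distance is binomial) plus
recorded node permutations; `make_two_group_cohort()` plants a connected
edge contrast for power studies.

What the phantoms deliberately do **not** emulate: diffusion physics,
crossing fibers, partial-volume effects, tractography error structure, or
spatially correlated noise. Passing tests demonstrate that the pipeline's
logic is correct under its own assumptions — exact recovery when the data
match the model, calibrated error rates under exchangeable noise — not
that real tractography satisfies those assumptions.

## Numerical choices and degenerate inputs

* Assignment ties (equidistant references) break to the lowest node index;
  component ids are numbered by lowest contained node. Both make runs
  bit-reproducible.
* All stochastic functions take an integer seed and restore the caller's
  RNG state; the annealing and rewiring use their own compiled-code
  generators keyed by the seed (one stream per restart).
* The exhaustive alignment oracle (`brute_force_align()`) enumerates all
  N! permutations and is capped at N ≤ 9.
* Degenerate inputs rejected with explicit errors: surfaces with < 4
  points or zero extent on an axis, single-point streamlines, asymmetric
  or nonzero-diagonal adjacency files, constant lower triangles in the
  correlation, disconnected input to `global_metrics()`, cohorts of one.
* Test-scale parameters: the suite and the acceptance study run with
  reduced ensembles (e.g. 5–100 random networks, 10–100 annealing
  restarts, NBS calibration over 200 simulations of 20 subjects at
  N = 20 with K = 200 permutations), chosen so the full suite completes
  in minutes while each check retains its statistical meaning. The
  reference parameter values (100 networks, 1000 rewires per edge, 100
  restarts, K = 1000) remain the config defaults.
* The Monte-Carlo equal-area check is asserted as a per-N chi-square
  goodness of fit within 3 sd of its expectation plus a 5-SE cap on any
  single region, rather than 3 SE per region: across the ~255 regions
  involved, independent 3σ tests would false-alarm with probability ≈ ½
  even though the areas are exactly equal (which the analytic check
  verifies to 1e-9).

## Known limitations

* Alignment quality degrades beyond ~100 nodes; the SA search is not a
  graph-isomorphism solver and offers no optimality certificate (the
  small-N oracle and planted-permutation recoveries are the evidence of
  adequacy at pipeline scale).
* Networks must have equal N to be aligned or compared; no emergence or
  disappearance of nodes.
* L is only defined on connected networks; the package restricts to the
  giant component explicitly rather than silently averaging reachable
  pairs.
* Weighted analysis is out of scope beyond carrying streamline counts.
* The pairwise correlation matrix is directional; summaries must say
  which direction they average (this package uses rows-as-reference).
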