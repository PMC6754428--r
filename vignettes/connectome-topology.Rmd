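---
title: "Group-level topology analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level topology analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structnet)
```

# The problem

Case–control studies of structural brain connectivity compare, across
two groups of subjects, weighted networks whose nodes are parcellated
grey-matter regions and whose edges are tractography-derived
connection probabilities. Three families of questions arise: *where*
does connectivity differ (edge-level inference with family-wise error
control), *how* does network organisation differ (hubs, communities,
rich-club structure, modular fingerprints), and *does* network
organisation relate to behaviour (confound-adjusted association with
clinical scores). `structnet` implements this chain as composable,
seed-deterministic functions plus a one-shot pipeline driver, and
ships a synthetic-cohort generator so that every stage can be
validated against planted ground truth.

# Preprocessing model

A subject enters as a directed matrix of connection probabilities
`P[i, j]` (probability that streamlines seeded in region i reach
region j). The chain is:

1. `volume_normalize()` — row i divided by region i's voxel count,
   removing the dependence of streamline counts on parcel size. The
   pipeline normalises before symmetrising, matching the order in
   which the quantities are defined; both operations are exposed
   separately so either order can be run, and they commute up to a
   global factor when all volumes are scaled equally.
2. `symmetrize_directed()` — undirected connectivity as the average
   of the two directed probabilities; diagonal zeroed.
3. `threshold_bottom_rank()` — among the E *existing* (nonzero)
   undirected links, the `floor(f·E)` weakest by weight are removed
   (default f = 0.01). The count base is existing links, not all
   N(N−1)/2 pairs, because the operation targets spurious weak
   *connections*; ties at the boundary break by lexicographic (i, j)
   order so the pipeline is reproducible.
4. `rescale_by_max()` — division by the matrix maximum puts subjects
   on a common scale (maximum weight 1) before graph analysis.

File I/O is deliberately plain: headerless square numeric TSV (CSV
sniffed) per subject, an atlas TSV (`id, label, hemisphere, x, y, z,
volume`; 0-based ids are shifted on read), and one covariates TSV.
Indexing is 1-based throughout the R API.

# Network-based statistics

`nbs_test()` computes a pooled-variance two-sample t statistic for
every upper-triangle edge present in at least one subject (positive t
= stronger in group B), thresholds `|t|` at the primary threshold
(default 2.1), and extracts connected components of the
supra-threshold graph. Significance of a component of extent s (edge
count) is assessed against the permutation distribution of the
*maximum* component extent under random relabelling of subjects
(group sizes preserved), with the +1-corrected estimate
`p = (1 + #{max ≥ s}) / (1 + n_perm)`, so p can never be zero and is
bounded below by `1/(1 + n_perm)`.

Numerical choices: a variance floor of 1e-24 keeps the statistic
finite when both groups are constant but unequal (equal constant
groups give t = 0); untested edges are `NaN`, never silently zero.
Thresholding on `|t|` is two-sided, so one component may mix
increases and decreases; per-edge signs are recorded from the t sign.
The permutation loop uses a union-find maximum-extent routine rather
than building a graph object per permutation; the user-facing
component extraction goes through igraph and both are cross-checked
against a BFS oracle in the tests.

The primary threshold is a sensitivity dial, not a validity dial:
FWER control holds at any choice. Liberal thresholds (2.1) suit
subtle, topologically extended effects; conservative ones suit strong
focal effects. The validation suite exercises both regimes: the
family-wise error simulation runs at t = 2.1 under a global null
(200 simulated studies, 20 nodes, 10 + 10 subjects, 500
permutations), and the power simulation plants a strong focal 5-edge
path (delta = 1, noise SD 0.05, 15 + 15 subjects) and tests it at
t = 3, where its detection is essentially certain. At a liberal
threshold a very strong focal effect partially re-enters the
permutation null through extreme label splits (a hypergeometric-tail
effect of a few percent), which caps attainable p-values near the
nominal level — the reason dataset-appropriate threshold choice is
part of the method.

# Graph measures

Edge weights map to lengths as `1/w` (the standard choice in weighted
connectomics; the strongest connection is the shortest). On these
lengths: nodal efficiency is the mean inverse distance from a node to
all others (`1/∞ = 0`), global efficiency the mean over ordered
pairs, local efficiency the global efficiency of each node's
neighbour subgraph. Weighted clustering follows Onnela (geometric
mean of triangle weights rescaled by the matrix maximum; binary
degree in the denominator). The characteristic path length of a
disconnected graph averages the finite pairs and carries a
`disconnected` flag plus a warning. The small-world index uses 100
degree-preserving randomisations by default.

Participation coefficient and within-module degree z-score use
*binary* degree, matching their classical definitions; both are
therefore invariant to global weight rescaling. Conventions for
degenerate cases: PC = 0 for isolated nodes; z = 0 for singleton or
zero-variance modules. All SDs in hub rules are sample SDs.

# Hubs, communities, fingerprints

`louvain_best()` runs Louvain `n_restarts` times (default 1000,
matching standard practice for this greedy, order-sensitive
optimiser), each restart permuting node order under a derived
sub-seed, and keeps the partition with maximal weighted modularity;
exact ties resolve to the lexicographically smallest canonical
assignment. On small graphs the result is verified against exhaustive
partition enumeration.

Hubs by efficiency: normalise `E_nodal` by its mean and flag nodes
above `1 + SD`. Taxonomy: nodes whose within-module z exceeds the
mean + SD of all nodes (the z-score is normalised across the whole
network, as the rule is stated) are *provincial* when PC ≤ 0.3 and
*connector* when PC > 0.3.

For group comparison of modular connectivity a single reference
partition is used. Each group's average matrix is partitioned; the
goodness-of-fit of a group partition is its mean normalised mutual
information (NMI) with the members' individual partitions, and the
group with the higher mean supplies the reference (ties fall back to
group A with a warning). NMI was chosen as the goodness measure
because it is the standard partition-similarity score with a [0, 1]
range; the group-average matrix (rather than consensus clustering)
supplies the group partition because it is the simplest estimator
consistent with how the group networks are built elsewhere in the
pipeline. Fingerprints count edges within each module, between each
module pair, and between module pairs restricted to connector-hub
incident edges; the counts conserve the total edge count by
construction. Four module-level metrics (mean binary degree, PC,
weighted betweenness on 1/w lengths, within-module z) are compared
across groups per module with permutation t-tests and BH-corrected
across all module × metric cells.

# Rich club

`weighted_phi()` at level k takes the subnetwork S of nodes with
binary degree > k and returns the ratio of the weight inside S to the
sum of the equally many strongest weights anywhere in the network —
1 means the club's connections are the strongest the network has.
Normalisation divides by the mean `Φ_random(k)` over degree-preserving
nulls (default 1000): Maslov–Sneppen double-edge swaps (10 per edge)
for the topology, then a random permutation of the weight multiset
over the rewired edges. Permuting weights, rather than carrying them
on swapped edges, is the stricter null — it destroys weight-topology
correlation as well as topology — and is the conventional choice for
weighted rich-club curves; graphs admitting no swap (stars) are
returned unchanged with a warning. Levels where the club is empty or
edgeless are reported as missing, never as zero. Because membership
at level k means degree *greater than* k, a planted core whose
degrees span `[d_min, d_max]` is the exact club for
`k ∈ [d_min − 1, d_max − 1]`; the validation suite asserts the
`Φ_norm` peak in that band. Rich-connector-hub networks intersect
club membership at a chosen k with connector-hub status and collect
existing edges from that intersection to any connector hub.

# Association statistics

`ttest_from_summary()` reproduces pooled two-sample t-tests from
printed group means/SDs/sizes (Student, df = n_a + n_b − 2); pooled
rather than Welch is the default because it reproduces published
demographic-table p-values at printed rounding, and it matches the
edgewise NBS statistic. `partial_correlation()` residualises metric
and score on the confounds (least squares with intercept; gender
coded 0/1) and tests the residual Pearson r on n − 2 − k degrees of
freedom; with no confounds this is numerically identical to the plain
Pearson test. Published r/p pairs for this analysis are not jointly
consistent with any single n under this formula, so the procedure —
not specific printed r values — is what the package validates, via
parameter-recovery simulation. No multiplicity correction is applied
to associations by default (mirroring how such exploratory
associations are usually reported); `fdr_bh()` is available and is
applied where the modular comparisons require it.

# The synthetic-cohort generator

`topology_spec()` describes the study conditions: 90 regions in seven
near-equal communities; within/between edge probabilities 0.7/0.12
(overall density ≈ 20%, in the empirical range for thresholded
probabilistic-tractography networks); mean weights 1.0/0.5 with
truncated-Gaussian noise SD 0.2 (truncated rather than lognormal for
direct moment control); 13 hub nodes whose incident edges are both
denser (presence floor 0.9) and stronger (weight × 2) — empirical
hubs combine high degree with high strength, and both ingredients are
needed for planted hubs to dominate the efficiency ranking; a 10-node
core (subset of the hubs) that is fully mutually wired at the top
weight scale, giving rich-club structure.

`generate_cohorts()` draws, by default, *one* edge topology per study
and lets subjects differ through weight noise. This mirrors the high
intra-group consistency of empirical structural connectomes; with
fully independent per-subject topologies, the union of half-present
edges makes the tested-edge universe at 90 regions so dense that the
supra-threshold graph becomes supercritical and the NBS permutation
null degenerates into a giant component — an artefact no consistent
cohort shows. Per-subject independent topology remains available
(`shared_topology = FALSE`) and is what `generate_connectome()`
produces standalone. Planted-effect edges are guaranteed present in
the backbone of *both* groups (a planted decrease requires an
existing connection); the default effect is a connected 71-edge
subgraph with 39 decreases and 32 increases of magnitude 0.3.

The covariate model plants
`score = intercept + slope · z(E_nodal(target)) + β_age·age +
β_gender·gender + ε`: the slope applies to the cohort-standardised
nodal efficiency, so the generating partial correlation is
`slope / sqrt(slope² + σ_ε²)` by construction and recovery can be
tested quantitatively. One master seed spawns all per-subject seeds
by fixed offsets.

What the generator does *not* emulate: distance-dependent wiring
costs, hemispheric homotopy, realistic streamline-count
distributions, or spatially autocorrelated noise. Passing tests
therefore demonstrate the correctness and statistical calibration of
the procedures, not their behaviour on every idiosyncrasy of real
diffusion data.

# Problem sizes used in validation

The test-suite simulations run at deliberately modest sizes chosen to
give stable pass/fail behaviour: the NBS null calibration uses 200
simulated studies of 20 regions (10 + 10 subjects, 500
permutations); power uses 50 studies at 15 + 15; oracle suites cover
500 random instances of up to 10 nodes (Floyd–Warshall efficiencies,
explicit rich-club sums, BFS components, exhaustive modularity up to
Bell(7) partitions); partition recovery uses 60-node four-module
graphs over 50 seeds; covariate recovery 100 studies of 15 subjects.
The acceptance script repeats these computations from scratch under a
caller-supplied seed and adds an end-to-end NBS analysis of the
default 90-region study.

# Known limitations

* Louvain with restarts is a heuristic; optimality is only guaranteed
  on the small graphs where enumeration verifies it.
* The NBS implementation covers two-group designs with pooled or
  (optionally, via the exported t-map functions) user-built
  statistics; regression/F designs and threshold-free enhancement are
  out of scope.
* Strength-based (weighted-degree) rich-club variants and
  between-group inference on `Φ_norm` curves are not implemented.
* Hub taxonomy uses the fixed PC = 0.3 convention; alternative cut
  points must be applied by the caller on the reported PC values.
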