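# structnet

Topology analysis of whole-brain structural connectomes for two-group
case–control studies.

Structural connectomes are weighted networks whose nodes are
parcellated grey-matter regions (e.g. the 90 cortical/subcortical
regions of the AAL atlas) and whose edges carry tractography-derived
connection probabilities. `structnet` implements the full group-level
analysis chain for such data:

* **Preprocessing** — seed-volume normalisation, symmetrisation of
  directed probabilities (`C_ij = (P_ij + P_ji)/2`), removal of the
  bottom-ranked 1% of links, and max-rescaling.
* **Network-based statistics (NBS)** — edgewise pooled two-sample
  t-maps, primary thresholding (|t| > 2.1 by default), connected
  component extent, and family-wise error control via the permutation
  null of the maximum component extent. Two-sided thresholding lets a
  single significant component mix increased and decreased
  connections, with per-edge signs reported.
* **Graph metrics** — nodal efficiency
  `E_nodal(i) = mean_j 1/d(i,j)` on edge lengths `1/w`, global/local
  efficiency, Onnela weighted clustering, characteristic path length,
  small-world index `σ = (C/C_rand)/(L/L_rand)` against
  degree-preserving nulls.
* **Communities and hubs** — weighted Louvain modularity
  `Q = (1/2m) Σ_ij (w_ij − s_i s_j/2m) δ(c_i, c_j)` with 1000
  restarts; efficiency hubs (normalised `E_nodal` above mean + SD);
  provincial vs connector hubs via within-module degree z-score and
  participation coefficient `PC(i) = 1 − Σ_c (k_ic/k_i)²` split at
  PC = 0.3; NMI-based selection of a reference partition; modular
  connectivity fingerprints (intra-, inter- and connector-hub-driven
  edge counts) compared across groups by permutation t-tests with BH
  correction.
* **Rich club** — weighted `Φ(k)` (within-club weight over the same
  number of top-ranked weights network-wide), normalised by
  degree-preserving, weight-permuting nulls; rich-connector-hub
  networks.
* **Associations** — partial correlation of network metrics with
  clinical scores adjusting for age and gender; summary-statistic
  pooled t-tests; Mann–Whitney/Kolmogorov–Smirnov/t group
  comparisons; BH FDR.
* **Synthetic cohorts** — a generator with planted modules, hubs, a
  rich-club core, a connected subnetwork of signed group differences
  and a planted covariate relation, so every stage can be validated
  against ground truth.

## Worked example

```r
library(structnet)

spec  <- topology_spec(seed = 11)                 # 90 regions, 7 modules
eff   <- default_effect_spec(90, delta_magnitude = 0.3)  # 71-edge mixed effect
study <- generate_cohorts(spec, eff, covariate_spec(target_node = 5),
                          n_per_group = 15)
study$A <- preprocess_cohort(study$A)             # 1% thresholding + rescale
study$B <- preprocess_cohort(study$B)

nbs_test(study$A, study$B, t_thresh = 2.1, n_perm = 1000, seed = 101)
#> <nbs_result> A vs B, |t| > 2.10, 1000 permutations
#>   component 1: 148 edges (45 increases, 103 decreases), p_fwer = 0.0010

part <- louvain_best(group_average(study$A), n_restarts = 100, seed = 7)
part
#> <partition> 7 modules, Q = 0.2030

hubs <- classify_hubs(group_average(study$A), part)
sum(hubs$is_hub)                                  # 13 efficiency hubs

curve <- normalized_rich_club(group_average(study$A), n_random = 100, seed = 9)
#> rich-club peak: phi_norm = 1.63 at k = 34
```

The NBS run finds one significant connected component containing the
planted signed differences (FWER-corrected p = 0.001); the group
network decomposes into the seven planted communities; thirteen
regions qualify as efficiency hubs; and the rich-club curve peaks
above 1 at high degree, marking a core more densely interconnected
than degree-matched chance.

The same analysis runs end to end from a config file:

```r
run_pipeline(run_config(out_dir = "run1",
                        simulate = list(n_per_group = 15),
                        master_seed = 1))
```

or from a shell via `inst/cli/structnet.R run --config run.yaml --out run1`.

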