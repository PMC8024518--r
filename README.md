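# netsweep

Group comparison of structural brain connectomes by density-sweep graph
analysis.

Structural connectomics estimates the white-matter wiring between brain
regions from probabilistic tractography: seed `S_i` streamlines in region
*i*, count how many (`S_i→j`) reach region *j*, and summarize connectivity
as the scaled conditional probability `P_ij = ((S_i→j / S_i) R_i +
(S_j→i / S_j) R_j) / 2` — a symmetric weighted network over an atlas (by
default 148 Destrieux cortical + 14 subcortical regions, 162 nodes). Because
graph metrics of weighted networks are threshold-dependent, the analysis
binarizes each subject's matrix at every density *d* in 0.02–0.20 (steps of
0.02), computes the topological indices at each density, and treats each
metric-versus-density **curve** as the unit of analysis, summarized by its
trapezoidal area under the curve (AUC).

The statistical core, for two groups (patients vs controls):

* **Global indices** — clustering coefficient *C*, characteristic path
  length *L*, global and local efficiency, transitivity, modularity *Q*,
  and the small-world family γ = C/⟨C_rand⟩, λ = L/⟨L_rand⟩,
  σ = γ/λ, with ⟨·⟩ means over degree-preserving (Maslov–Sneppen)
  rewired reference graphs.
* **Permutation inference** — the observed statistic is the difference of
  group-mean AUCs; the null reassigns subjects' curves to groups of the
  original sizes (1,000 permutations by default), with
  p = (1 + #{|t_null| ≥ |t_obs|}) / (B + 1).
* **Regional tests** — the same comparison per node (degree, betweenness,
  clustering, local efficiency), Benjamini–Hochberg FDR-corrected across
  nodes; hubs are nodes whose centrality-curve AUC exceeds mean + 2 SD of a
  reference distribution (permutation ensemble or across-node, both
  implemented).
* **Associations** — Spearman ρ between topology AUCs and clinical
  variables (e.g. lowest lifetime BMI), Mann–Whitney U for clinical group
  differences, lobe averaging, and OLS regressions of per-node group
  differences in metric AUC on group differences in cortical volume.

A synthetic cohort generator (Watts–Strogatz skeletons with group-specific
rewiring, negative-binomial streamline counts, planted hubs, and clinical /
volumetric couplings with known slopes) provides ground truth for
calibration and parameter-recovery testing of every stage.

## Worked example

Simulate a cohort of 8 + 8 subjects in which patients have a more rewired
(less clustered) latent skeleton than controls and six hub regions are
planted in both groups, then run the full pipeline:

```r
library(netsweep)

report <- run_pipeline(list(
  seed = 42,
  synthetic = list(n_per_group = 8, rewire_prob_group_a = 0.22,
                   rewire_prob_group_b = 0.08, n_planted_hubs = 6,
                   hub_boost = 3),
  sweep = list(n_random_refs = 5),
  permutation = list(n_permutations = 200,
                     hub_rule = "within_network_2sd")))

dplyr::select(report$global_tests, metric, mean_auc_a, mean_auc_b,
              observed_stat, p_value)
#> # A tibble: 7 × 5
#>   metric                mean_auc_a mean_auc_b observed_stat p_value
#>   <chr>                      <dbl>      <dbl>         <dbl>   <dbl>
#> 1 small_world_index         0.364      0.557       -0.193   0.00498
#> 2 normalized_clustering     0.375      0.615       -0.240   0.00498
#> 3 local_efficiency          0.0734     0.0871      -0.0137  0.00498
#> 4 transitivity              0.0327     0.0434      -0.0107  0.00498
#> 5 modularity                0.0599     0.0720      -0.0120  0.00498
#> 6 global_efficiency         0.0894     0.0877       0.00171 0.00498
#> 7 char_path_length          0.416      0.437       -0.0213  0.00498
```

Each row compares the AUC of one global metric's curve between groups
(`a` = patients, `b` = controls). The planted rewiring difference shows up
exactly where it should: patients have lower small-world index and lower
normalized clustering (negative `observed_stat`, the group-mean AUC
difference), at the smallest p-value 200 permutations can produce
(1/201 ≈ 0.005). The hub table recovers the six planted hubs:

```r
dplyr::filter(report$hubs, is_hub, criterion == "degree",
              group == "control")[, c("node_id", "score", "threshold")]
#> # A tibble: 6 × 3
#>   node_id score threshold
#> 1 139      7.82      4.84
#> 2 16       7.26      4.84
#> 3 27       6.97      4.84
#> 4 47       6.84      4.84
#> 5 54       7.17      4.84
#> 6 70       7.4       4.84
```

`score` is the node's group-mean degree-curve AUC and `threshold` the
across-node mean + 2 SD cut. Real data enter the same pipeline through
`inputs = list(counts_dir=, node_table=, clinical=, volumes=)` instead of
`synthetic`, or through the lower-level functions
(`compute_probability_matrix()`, `sweep_cohort()`, `fda_auc_test()`,
`regional_tests()`, `identify_hubs()`, `spearman_assoc()`,
`volume_topology_regression()`), all of which return tibbles or objects
with `tidy()`/`glance()`/`autoplot()` methods. A thin command-line wrapper
lives at `inst/scripts/netsweep.R` (subcommands `simulate`, `build`,
`metrics`, `compare`, `hubs`, `associate`, `run-all`).

See `vignettes/density-sweep-connectomics.Rmd` for the full account of the
models, conventions, defaults and limitations.

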