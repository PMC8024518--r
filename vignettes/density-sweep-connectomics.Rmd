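---
title: "Density-sweep connectome group comparison: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-sweep connectome group comparison: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netsweep implements a complete group-comparison analysis for structural
white-matter connectomes estimated by probabilistic tractography. This
vignette explains the statistical machinery, the defaults and why they were
chosen, what the synthetic cohort generator does and does not emulate, and
the numerical corner cases.

## From streamline counts to connectivity matrices

Probabilistic tractography seeds a fixed number of streamlines $S_i$ in each
region of interest (ROI) $i$ and counts how many, $S_{i \to j}$, reach each
target region $j$. The directed connection estimate is the scaled conditional
probability

$$d_{ij} = \frac{S_{i \to j}}{S_i}\, R_i,$$

where $R_i$ is an optional per-ROI scale factor. Because
$d_{ij} \approx d_{ji}$ but not exactly, the two directed estimates are
averaged, $P_{ij} = (d_{ij} + d_{ji})/2$, giving an exactly symmetric,
zero-diagonal weighted network. `compute_probability_matrix()` enforces all
of this and refuses degenerate inputs (zero seed totals, counts exceeding
seeds).

$R_i$ defaults to 1, which keeps $P_{ij}$ a plain conditional probability.
If a user wants seed-region size folded in (e.g. proportional to the number
of boundary voxels), the `scale` column of the node table carries it. The
arithmetic mean was chosen for symmetrization; any symmetric combination
would do, and the mean is the convention in the toolbox lineage this design
follows.

The default node table is the 148-region Destrieux cortical parcellation
plus 14 subcortical regions (162 nodes), with hemisphere and lobe labels.
Lobe assignments for sulci straddling boundaries follow the lobe holding
most of their extent; they matter only for the lobe-averaged summaries, not
for any graph metric.

## Nuisance covariates

Age and handedness (Edinburgh laterality index) effects are removed by
ordinary least squares across subjects, feature by feature, with the
feature's grand mean added back so residualized values stay on their
original scale; edge weights are floored at zero afterwards. Whether the
residualization target should be edge weights or derived metric curves is
not decidable from the method lineage alone, so both modes exist
(`residualize = "edges"` or `"none"` in the pipeline, plus `residualize()`
usable on any subjects-by-features matrix). Edge-level residualization
before thresholding is the default. The operation is idempotent and
mean-preserving; collinear covariates are dropped with a warning rather
than silently pseudo-inverted.

## The density sweep

Weighted matrices are binarized by retaining the $E = \mathrm{round}(d \cdot
N(N-1)/2)$ largest-weight edges at each density $d$ of the grid 0.02 to 0.2
in steps of 0.02 (10 points, endpoints inclusive). Tie-breaking is
deterministic: descending weight, then ascending $(i,j)$ pair, which makes
runs reproducible and edge sets nested across the sweep. If a matrix has
fewer nonzero weights than $E$, all nonzero edges are kept and a
density-shortfall warning is raised — on sparse data this is the silent
failure mode of density sweeps, so it is never swallowed. The per-density
number of connected components is reported alongside for the same reason.

## Graph metrics

All indices are computed on the binary graphs:

* segregation: mean clustering coefficient $C$, mean local efficiency,
  transitivity $T$, modularity $Q$;
* integration: characteristic path length $L$, global efficiency
  $E_{glob}$;
* centrality (nodal): degree and betweenness (raw Brandes counts and
  normalized by $(N-1)(N-2)/2$; regional tables report both since
  published regional values are frequently on unstated scales).

Conventions where definitions fork:

* $L$ averages over **connected pairs only**; disconnected graphs are not
  assigned infinite path lengths, and the component count is surfaced
  instead. This matches the graph-analysis toolbox lineage.
* Local efficiency of a node is the global efficiency of the subgraph
  induced by its neighbors (the node itself removed), the Brain
  Connectivity Toolbox convention. This is implemented directly; igraph's
  `local_efficiency()` measures neighbor-pair distances in the full graph
  minus the node, which is a different quantity.
* Local clustering of nodes with fewer than two neighbors is 0, and
  transitivity of a graph without connected triples is reported as 0.
* $Q$ is maximized by deterministic agglomeration: three starts
  (Clauset–Newman–Moore greedy, multilevel with a fixed internal seed whose
  RNG state is restored, and leading-eigenvector), each polished by
  deterministic single-node moves until no move improves $Q$, keeping the
  best. Agglomerative $Q$ can still undershoot the exhaustive optimum; the
  test suite checks it stays within 10% of an exhaustive-partition oracle
  on at least 95% of small random graphs.

### Small-world normalization

Normalized clustering $\gamma = C/\langle C_{rand}\rangle$ and normalized
path length $\lambda = L/\langle L_{rand}\rangle$ divide by means over
degree-preserving random references built by Maslov–Sneppen double-edge
swaps (10 attempted swaps per edge, 20 references by default; both
exposed in `sweep_config()` since the literature rarely states them). The
Small-World Index is $\sigma = \gamma/\lambda$. On density-matched
Erdős–Rényi graphs $\gamma$ and $\sigma$ sit near 1, which the tests verify
to within 0.15; ring lattices with mild rewiring at $N = 162$, $k \approx
10$ give $\sigma$ well above 2. If a reference draw has zero clustering —
possible for very sparse graphs — $\gamma$ is reported as `NA` with a
warning rather than an infinity; analyses of small sparse synthetic
networks should start their grid at densities where triangles exist.

Published $\gamma$ values for dense whole-brain parcellations can be far
larger than anything degree-preserving rewiring produces on synthetic
lattices; no attempt is made to tune the reference model toward any
particular magnitude.

## Group inference

The unit of analysis is the metric-versus-density **curve**; its trapezoidal
area under the curve (AUC) over the grid is the threshold-free summary. The
test statistic is the difference of group-mean AUCs (group A minus group B,
patients first by pipeline convention). The null distribution reassigns
subjects' curves at random to two groups of the original sizes;
$p = (1 + \#\{|t^{null}| \ge |t^{obs}|\})/(B + 1)$ with $B = 1000$
permutations by default. The +1 correction avoids zero p-values at finite
$B$. Because the statistic is linear in per-subject AUCs under a shared
grid, comparing AUCs of mean curves and means of per-subject AUCs are the
same thing; the subject-level formulation is the default. A group-level
mode (`group_auc_test()`) that rebuilds one mean matrix per permuted group
and re-runs the sweep each time exists for the covariance-toolbox reading
of the procedure; it is far slower and intended for small cohorts.

Regional tests run the same comparison per node with a shared permutation
stream and adjust raw p-values with Benjamini–Hochberg FDR across nodes.

### Hubs

A node is a hub when its group-mean AUC of a centrality curve (degree or
betweenness) exceeds mean + 2 SD of a reference distribution. Two readings
of the reference coexist in the literature and both are implemented:

* `permutation_2sd` (default): the node's own permutation ensemble of
  group-mean AUCs. This flags nodes whose centrality is high *relative to
  label exchange* — it is sensitive to group-specific hubness.
* `within_network_2sd`: the distribution of scores across all nodes of the
  same group. This is the conventional "hubs of a network" reading and is
  the one that recovers planted hubs in synthetic cohorts.

Neither rule was calibrated against any published hub table; the rule used
is always recorded in the output.

## Clinical and volumetric associations

Spearman correlations (average-rank ties, two-sided t approximation) link
topology AUCs to clinical variables, uncorrected at $p < 0.05$ by design —
the analysis is exploratory and is reported as such. Group comparisons of
clinical variables use the Mann–Whitney U test with tie-corrected normal
approximation, z reported as positive magnitude plus direction. The
volumetric analysis regresses per-node group differences in metric AUC on
per-node group differences in mean cortical volume (control minus patient
by default; configurable), per lobe and overall, by ordinary least squares.
Node-level points are the observations within each lobe; volume differences
can be expressed raw or as percent of the control mean.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage has a
parameter-recovery test against known ground truth. Its latent model:

* Each subject's white-matter skeleton is a Watts–Strogatz ring lattice
  ($N$ nodes, $k$ neighbors, defaults 162 and 10) rewired with the
  subject's group-specific probability. Rewiring directly manipulates
  clustering and small-worldness — exactly the quantities the analysis
  targets — which makes planted group differences interpretable.
* A small Gaussian jitter (SD 0.02) on the rewiring probability carries
  individual small-worldness; its standardized negative value is the
  subject's latent small-worldness score, which links to simulated lowest
  lifetime BMI with slope `bmi_swi_effect` plus unit-scale noise. BMI
  values are shifted into plausible clinical ranges (patients around
  14–17 kg/m², controls around 19–22), though all tests use only
  correlations, not locations.
* Directed streamline counts are sampled independently per direction as
  negative binomial with mean `edge_weight_scale` (default 50) times the
  latent weight and dispersion `count_noise` (default 0.5; 0 gives
  Poisson) — streamline counts are overdispersed nonnegative integers.
  Seed totals default to 5000 streamlines per ROI. Non-skeleton pairs
  carry a weak background weight (2% of a skeleton edge) so that
  thresholding above the skeleton's density recruits noise edges, as real
  tractography does; subject-to-subject count variability is not
  characterized in the literature this emulates, so the dispersion default
  is a deliberate, exposed choice.
* Planted hubs multiply every incident weight (skeleton and background) by
  `hub_boost`, so hubs carry both more streamline mass and more
  supra-threshold connections at every density — making them hubs of the
  realized binary networks, not only of the weight matrix.
* When `volume_effect` is nonzero, control subjects receive per-node
  strength boosts $\delta_j \sim U(0, 0.5)$ mirrored in their volume means,
  planting the positive volume-difference-versus-centrality-difference
  association that the regression stage is tested to recover.

What the generator does **not** emulate: diffusion signal, tract geometry,
distance-dependent connection probability, hemispheric asymmetries,
spatially correlated noise, or realistic degree distributions of cortical
networks. Passing recovery tests therefore demonstrates that the
*statistical machinery* is correct and calibrated — not that any particular
empirical claim about patients generalizes.

## Study sizes used by the test suite

The acceptance-level checks run simulation studies sized for a desk-scale
single-CPU budget, stated here as the package's own choices:

* metric correctness: every labeled graph on up to 6 nodes against
  brute-force enumeration oracles; modularity against an
  exhaustive-partition oracle on 200 random graphs of up to 8 nodes;
* calibration: 200 null cohorts of 12 + 12 subjects on 40-node networks
  ($k = 8$), densities 0.12–0.20, one random reference (5 swaps per edge),
  200 permutations — the permutation test's size depends on none of the
  scaled-down quantities;
* power and recovery: 50 cohorts of 36 + 36 subjects on the full 162-node
  atlas for the clustering effect (rewiring 0.30 versus 0.05); 20 cohorts
  of 8 + 8 for hub recovery (6 hubs, boost 3) and for the volume-effect
  regression.

## Numerical and degenerate-input policy

Exact symmetry is enforced by construction, not by tolerance. Thresholding
an all-zero matrix, metrics on an empty or sub-3-node graph, constant
inputs to correlation, identical samples in the U test, and zero-variance
regression predictors all raise typed errors naming the problem; zero-
variance hub reference distributions degrade to threshold-equals-mean with
a warning. Matrix TSV round-trips are exact to $10^{-12}$; all permutation
and simulation streams are seeded, and one master seed fans out to fixed
per-stage offsets so any stage can be re-run in isolation.

## Known limitations

* The analysis binarizes; no weighted-metric variants are provided.
* Greedy modularity is a lower bound on the optimum.
* The FDA-style comparison is operationalized as the AUC difference; no
  pointwise curve-band inference is offered.
* Hub detection inherits the ambiguity of its published description; both
  readings are provided rather than adjudicated.
* Clinical correlations are uncorrected by design; treat them as
  exploratory.
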