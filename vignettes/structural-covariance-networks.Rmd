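---
title: "Group-level structural covariance network analysis with scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The problem

Regional cortical morphometry — surface area (SA, mm²) or mean cortical
thickness (CT, mm) per atlas parcel — covaries across individuals: regions
that mature, scale or degenerate together show correlated measures across a
population. Correlating every pair of regions across the subjects of one
diagnostic group yields a *structural covariance network* whose topology can
be compared between groups even when no single region differs on average.

`scnet` implements this group-level workflow for multi-site case–control
cohorts: harmonization of site scale, covariate regression, network
construction over a link-density grid, graph-theoretic characterization
(clustering, path length, efficiency, small-worldness, eigenvector-centrality
hubs, strength assortativity), consensus community detection with a modular
segregation contrast, and site-stratified permutation inference. A synthetic
cohort generator with planted covariance structure makes every stage testable
without access to restricted imaging data.

## The model, stage by stage

### Site harmonization by MAD rescaling

Multi-site cohorts mix scanners and protocols, so the same region is measured
on different scales at different sites. For each site and each region we
compute the raw median absolute deviation
\[
\mathrm{MAD} = \mathrm{median}_i\,\lvert x_i - \mathrm{median}_j x_j\rvert
\]
across the site's subjects (both groups jointly) and divide each subject's
value by it, giving a dimensionless "ratio of MAD". We deliberately omit the
1.4826 Gaussian consistency factor: it is constant per (site, region) and
cancels in every downstream correlation. `mad_rescale()` accepts an optional
larger reference table when MADs should be estimated on a superset of the
analyzed subjects (e.g. all of a site's quality-controlled scans rather than
the matched subsample). After rescaling, the per-(site, region) MAD equals 1
exactly; a zero MAD (constant data) is an error naming the site and region.

MAD rescaling controls *scale*, not *location*. Because the per-region MADs
are estimated from finite samples, small site-level location offsets of order
(mean/MAD) × (relative MAD error) survive rescaling; the covariate regression
(whose global-mean covariate tracks these offsets) absorbs most of the rest.
`site_bias_check()` quantifies what remains: per group, each site's
subject-level whole-cortex means are tested against the grand mean with a
one-sample t test, FDR-corrected across sites. On synthetic scale-confounded
cohorts, the confounded site is flagged reliably before correction and at
near-nominal rates after rescaling plus regression (see
`test-preprocess.R`).

### Covariate regression

Per region, `regress_covariates()` fits ordinary least squares of the
rescaled measure on intercept, age (years), sex (male = 1, female = 0) and
the subject's global mean of the same measure, and keeps the residuals. The
table passed in is one regression stratum; callers split by age band first.
Two open choices were resolved as follows:

* **Pooling across diagnostic groups.** The regression is fitted on both
  groups jointly (a `by_group` switch restores separate fits). Pooled
  residuals are exchangeable under a group-label permutation, which keeps the
  permutation null exact; group-specific fits would make each permutation
  draw depend on the relabeling.
* **Rank deficiency.** A stratum in which a regressor is collinear (e.g. a
  single-sex stratum, or a global mean that is an exact linear function of
  age) drops the offending column with a warning rather than failing.

### Network construction

`build_covariance()` Pearson-correlates all region pairs across one group's
subjects: for \(R\) regions there are \(R(R-1)/2\) unique connections
(10,878 at the 148-region Destrieux parcellation). `threshold_density()`
removes self- and non-positive connections, ranks the rest by correlation and
keeps the strongest \(k = \mathrm{round}(d \cdot R(R-1)/2)\) at density
\(d\); the denominator counts *all* pairs, so \(d\) is a fraction of possible
connections. Rounding of \(k\) (rather than flooring) is assumed; ties at the
cutoff are broken by the lexicographic region-index pair so that repeated
runs are bit-identical. Graphs over `density_grid()` are nested by
construction. The default analysis grid is 8–35% in 1% steps — the
conventional range in which group covariance networks are fully connected at
the lower end and not yet random at the upper end; `characteristic_path_length()`
reports a `disconnected` flag so connectivity is observable at any density.

### Graph metrics

All metrics operate on the binarized graphs.

* Clustering coefficient: Watts–Strogatz local clustering, computed as
  \(\mathrm{diag}(A^3)/(k(k-1))\); degree-0/1 nodes score 0 (the Brain
  Connectivity Toolbox convention). The network value is the unweighted node
  mean.
* Characteristic path length \(L\): mean shortest path over reachable pairs,
  with a disconnected flag when pairs were dropped.
* Global efficiency: the package default is the literal \(E = 1/L\). The
  Latora–Marchiori form (mean inverse distance) is available as
  `variant = "mean_inverse_distance"`; the two differ on any graph whose
  distances vary (on the 3-node path: 0.75 vs 5/6), and both are exposed
  because either convention is common in this literature.
* Small-worldness: Humphries–Gurney
  \(\sigma = (C/C_{rand})/(L/L_{rand})\) against degree-preserving
  Maslov–Sneppen surrogates (default 100 surrogates, \(10\lvert E\rvert\)
  attempted swaps each). The surrogate count and rewiring scheme are the
  standard Brain Connectivity Toolbox workflow. \(\sigma \approx 1\) on
  Erdős–Rényi graphs and \(\sigma > 1.5\) on a 10%-rewired Watts–Strogatz
  ring (asserted in the acceptance suite).
* Eigenvector centrality: the leading eigenvector of the adjacency matrix,
  fixed to the nonnegative (Perron) sign and unit Euclidean norm via a dense
  symmetric eigendecomposition — deterministic, no iteration-convergence
  ambiguity. Hub profiles (`hub_profile()`) average centrality over the
  coarse 5–35%/5% grid, z-score across regions, and call hubs at z > 1.5.
* Assortativity: the strength-assortativity coefficient over edges,
  \[
  r = \frac{M^{-1}\sum_i j_i k_i - \bigl[M^{-1}\sum_i \tfrac{1}{2}(j_i + k_i)\bigr]^2}
           {M^{-1}\sum_i \tfrac{1}{2}(j_i^2 + k_i^2) - \bigl[M^{-1}\sum_i \tfrac{1}{2}(j_i + k_i)\bigr]^2},
  \]
  with the density-averaged eigenvector centralities supplied as nodal
  strengths \(j_i, k_i\). Every metric is validated against an independent
  brute-force implementation (triangle enumeration, Floyd–Warshall, power
  iteration, edge-loop formula evaluation) on random graphs.

### Consensus modules and segregation

Louvain community detection (resolution 1.0, igraph backend, node order
randomized per seed) runs on the *weighted* positive-correlation network, so
module structure does not depend on the density grid. Because single runs are
local optima, `consensus_partition()` repeats Louvain 150 times, forms the
agreement matrix \(D_{ij}\) (fraction of runs co-assigning \(i\) and \(j\)),
zeroes entries below 0.5, re-clusters the pruned matrix 100 times, and
iterates until all runs agree (cap: 20 iterations, then an error — the cap is
a safeguard; planted-structure simulations converge in one or two).

The segregation index of a module with correlation matrix entries \(r\) is
\[
\mathrm{SI} = \frac{\bar{Z}_w - \bar{Z}_b}{\bar{Z}_w},
\]
where \(\bar{Z}_w\) is the mean Fisher-transformed correlation over
within-module pairs and \(\bar{Z}_b\) over all module × non-module pairs
(unweighted by module sizes). Correlations are clipped to
\(\pm(1-10^{-7})\) before `atanh` so degenerate synthetic inputs stay finite.
`transfer_si_contrast()` imposes the *case* group's partition on both groups
and returns the SI difference — the statistic for the permutation test, under
the null that the module is equally segregated in both groups.

### Center-paired permutation inference

Group differences are tested by rebuilding both pseudo-group networks under
random relabelings. `center_paired_shuffle()` permutes group labels
*within each site*, preserving every site's per-group counts; unrestricted
shuffling in multi-site data lets entire sites drift into one pseudo-group,
so site effects masquerade as group effects. The package keeps an
unstratified mode purely as a comparison harness; on synthetic cohorts with a
site-scale confound and unbalanced site-by-group composition, the
unstratified scheme's false-positive rate explodes while the stratified one
stays nominal (acceptance suite).

Two-tailed p-values use the empirical null with the add-one correction,
\(p = (1 + \#\{\lvert d^\ast\rvert \ge \lvert d\rvert\})/(B_{valid} + 1)\), and
the 95% null band is reported for plotting. Reading the "CI-derived p" as the
empirical-null tail probability (rather than inverting a Gaussian CI) keeps
the test exact and distribution-free. Permutations act on post-regression
residuals — the pooled regression makes residuals group-agnostic — so only
networks, not regressions, are rebuilt per draw, keeping thousands of draws
tractable. Statistics that fail on a permuted split (e.g. a degenerate SI)
are recorded as failed draws; more than 1% failures aborts. FDR correction is
Benjamini–Hochberg within a declared family; the pipeline's family is the
density grid within each metric within each age band.

## The synthetic cohort generator

`synthetic_config()`/`generate_cohort()` emulate the statistical structure
the pipeline assumes: several sites with different measurement scales, two
covariate-matched groups, age/sex/global effects, and block-structured
inter-regional correlation. Region values follow a nonnegative latent factor
model: with total variance \(T = \sigma^2/(1-\rho_w)\), every region loads
\(a = \sqrt{\rho_b T}\) on a shared factor and \(b = \sqrt{(\rho_w-\rho_b)T}\)
on its module's factor, giving expected correlations \(\rho_w\) within and
\(\rho_b\) between modules, and guaranteeing a positive-semidefinite
correlation matrix. Covariate matching is implemented by cloning the age/sex
draws across groups (a matched-pairs design), site scale multiplies the whole
subject record, and the generator is bit-reproducible from its seed.

An optional *split module* models a module that exists only in the case
group: in group B, the split module's regions divide into two sub-blocks
whose cross-correlation drops by `split_strength`. The default
`split_strength = 0.5` (with the default \(\rho_w = 0.6, \rho_b = 0.1\))
drops the cross-sub-block correlation to the between-module background — the
regime in which the sub-blocks genuinely *are* distinct modules and a
community detector can find them. Weaker splits leave the sub-blocks more
correlated with each other than with the rest of the network, so the planted
"extra module" is not recoverable even in principle at realistic sample
sizes; no effect size for module emergence is available from real-data
reports, so this calibration is the package's own choice.

What the generator does **not** emulate: spatial autocorrelation on the
cortical sheet, heavy-tailed or skewed measure distributions, site
differences beyond pure scale (e.g. site-specific covariance), missing data,
and FIQ effects on structure. Passing tests therefore demonstrate
correctness of the machinery under the factor-model assumptions, not
robustness to every property of real morphometry.

## Numerical and design choices

* **Tie-breaking and determinism.** Every stochastic stage takes a seed;
  `run_pipeline()` derives all stage seeds from one top-level seed via a
  seeded draw, and rerunning a configuration yields byte-identical artifact
  files. Correlation ties at the density cutoff are broken lexicographically.
* **Eigenvector sign/norm.** Perron sign, Euclidean norm 1; hub calls are
  invariant to the norm because of the z-scoring.
* **Disconnected graphs.** \(L\) restricts to reachable pairs and flags the
  graph instead of returning infinity; the default 8% lower density bound
  makes this rare in practice.
* **Global-mean regression and planted contrasts.** Regressing the subject
  global mean (like global-signal regression) shifts between-region
  correlations downward by a group-dependent amount in a pure factor model,
  which can cancel a planted segregation contrast almost exactly. The
  segregation power analyses therefore run on MAD-rescaled data without the
  global-mean stage; the regression stage is validated separately. Real
  cohorts, where global covariance is not exhausted by one factor, are less
  affected, but the interaction is worth knowing about when interpreting SI
  contrasts.
* **Permutation families for curve metrics.** The pipeline's default
  permutation family covers clustering, path length and efficiency (and the
  assortativity curve when configured). Small-worldness inside a permutation
  loop multiplies cost by the surrogate count, and modularity requires a
  Louvain run per draw; their observed curves are always reported, and both
  can be added to the permuted family via `perm_metrics` when the budget
  allows.
* **Q curves.** Modularity over the density grid is computed from each
  group's consensus partition by default (stable across densities); a
  per-density Louvain option exists in `modularity_q()` by passing any
  partition of interest.

## Problem sizes used in the validation suite

The test and acceptance suites run at deliberately reduced scale chosen to
exercise every code path with stable Monte-Carlo margins: cohorts of 24–60
regions (148 only for the connection-count check), 75–150 subjects per group,
permutation counts of 500–1000, 100–200 simulated null cohorts for
calibration, 150 + 100 Louvain runs for consensus (the full defaults), and 50
surrogates for small-worldness calibration. The pipeline defaults
(`pipeline_config()`) carry the full-scale study parameters: 5,000
permutations, 100 surrogates, 8–35% density grid, 5–35% hub grid, hub
threshold z > 1.5, consensus 150/100 with agreement threshold 0.5, age bands
7–11, 12–17 and 18–29 years.

## Known limitations

* Only binary-graph metrics are provided (no weighted clustering or
  efficiency variants); the community stage is the only weighted analysis.
* No partial correlations, covariance regularization, or individual-level
  networks — the network is a group-level object, so subject-level inference
  is out of reach by design.
* No ComBat-style location/scale harmonization; MAD rescaling addresses scale
  only, and the site-bias check is the guardrail.
* The consensus procedure can in principle fail to converge within its
  iteration cap on adversarial weight matrices; it then errors rather than
  returning an unstable partition.

## A minimal run

```{r example, eval = FALSE}
cohort <- synthetic_config(
  n_regions = 60, n_modules = 4, n_sites = 3,
  per_site_counts = c(50, 50, 50),
  split_module = 1, seed = 7)

cfg <- pipeline_config(
  input = cohort,
  age_bands = list(all = c(0, 100)),
  densities = seq(0.08, 0.35, by = 0.01),
  n_perm = 1000, seed = 7, out_dir = "scnet-demo")

res <- run_pipeline(cfg)
res$all$si_table          # segregation contrasts, case partition transferred
res$all$curves$A          # observed metric curves, group A
```
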