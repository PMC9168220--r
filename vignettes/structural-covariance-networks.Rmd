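---
title: "Structural covariance network contrasts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network contrasts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scna)
```

## The analysis in one paragraph

Structural covariance analysis asks how regional brain morphometry covaries
*across subjects* within a group: if one subject's cortex is thicker than
average in region A, is it also thicker in region B? Correlating every pair
of regions yields one weighted graph per group — not per subject — so group
comparisons cannot lean on subject-level statistics and instead use
permutation tests on graph-level summaries. This package implements that
pipeline end to end: confound regression, Pearson structural covariance
graphs per group for cortical thickness (CT), surface area (SA) and mean
curvature (MC) (each extended with non-cortical volumes to 87 regions),
directed cross-property covariance graphs on the 68 cortical regions,
density-thresholded weighted graph metrics reduced to area-under-curve
(AUC) summaries, and permutation contrasts with Benjamini–Hochberg false
discovery rate (FDR) control. A latent-factor synthetic cohort generator
with plantable group effects makes every stage testable without access to
clinical imaging data.

## Covariance graphs

For a residualized subjects-by-regions matrix, the same-property graph has
weights `SC[i, j] = cor(region i, region j)` across subjects (Pearson,
unbiased normalization — any consistent choice cancels in the
correlation). Negative edges are set to zero: downstream weighted metrics
(degree as a sum of weights, geometric-mean triangle intensities,
Perron–Frobenius centrality) are meaningful only on nonnegative weights.
The share of surviving edges is recorded as `retained_fraction`.

The cross-property graph correlates property 1 in region i with property 2
in region j, for all ordered pairs of cortical regions. The result is
asymmetric — entry (i, j) and entry (j, i) answer different questions — so
it is treated as a directed graph; self-loops (the diagonal) are removed
and negative edges excluded as before.

## Density thresholding

Because absolute correlation levels differ between groups and properties,
graphs are compared at matched *densities*: the strongest
`round(rho * E_max)` edges are kept (weights preserved, not binarized),
where `E_max` counts unordered region pairs for symmetric graphs and
ordered pairs for directed ones — in/out-degree distinguishes direction, so
density must too. The default grid sweeps 20% to 60% in 1% steps (41
points):

* below ~20% the observed group graphs are no longer guaranteed to be
  fully connected, which eigenvector centrality requires;
* above ~60% the positive-edge budget runs out (the generator is
  calibrated so this holds, mirroring empirical morphometry, where
  roughly 67–85% of edges survive negative-edge exclusion).

Numerical choices, all deterministic: edge counts round half up with a
relative epsilon so binary float representation cannot shift a count; ties
at the cut break by descending weight then ascending (row, column) index,
which also makes edge sets nested along the grid. The step size is
configurable; AUC magnitudes scale with the number of grid points, so
every AUC output records its grid.

The full-connectivity guard at the lowest density applies to observed
same-property graphs only: eigenvector centrality is uniquely defined only
on connected graphs, whereas the row/column sums used on directed graphs
need no connectivity. Permuted (null) graphs are exempt from the guard —
discarding them would bias the null — and fall back to per-component
eigenvector centrality instead.

## Graph metrics and the AUC reduction

Per region and density the package computes weighted degree (sum of
incident weights), the Onnela-style weighted clustering coefficient
(geometric mean of triangle weights, rescaled by the maximum weight; the
binary variant is available behind a flag), and eigenvector centrality
(leading eigenvector, nonnegative orientation, unit Euclidean norm) for
same-property graphs; directed graphs get in-degree (column sums) and
out-degree (row sums). Each regional metric-versus-density curve is reduced
to its AUC, implemented as the plain sum over grid points: summing
differences and differencing sums then agree exactly by linearity, so
"difference of AUCs" and "sum of differences across densities" are provably
the same statistic.

Inside the density sweep the adjacency is grown incrementally (nestedness
makes that exact), clustering is updated edge-by-edge through the
closed-3-walk identity, and eigenvector centrality is warm-started from the
previous density's vector by power iteration (tolerance 1e-10 in sup norm)
with a dense-eigendecomposition fallback that also covers
bipartite-degenerate spectra, where plain power iteration oscillates. All
paths are deterministic, and the test suite checks them against direct
per-density recomputation and brute-force oracles.

## Permutation inference

For a contrast A − B the observed statistic is the per-region AUC
difference, per subcase. The null is built by rerunning the *entire*
chain — confound regression onward — after randomly reassigning the pooled
subjects to two pseudo-groups of the original sizes. For the paired
post-minus-pre contrast a `paired_swap` scheme is also provided, flipping
pre/post labels independently per subject pair; which scheme matches a
given study design is the analyst's call, and both are exposed.

Two details keep the machinery exact:

* Pseudo-group draws and pooling are *role-symmetric* (pooled rows are in
  alphabetical group order and the sampled subset always plays the
  alphabetically first group), so reversing a contrast negates every null
  delta exactly and leaves p-values unchanged.
* Assignments under which a pseudo-group graph cannot reach the top grid
  density are redrawn (at most 10 attempts, counted and reported), keeping
  exactly `n_permutations` null rows.

P-values are two-sided with the add-one estimate,
`p = (1 + #{|null| >= |obs|}) / (n + 1)`, which never returns zero and is
exact under exchangeability. FDR correction is Benjamini–Hochberg, by
default pooled over all regions and subcases of one contrast (9 × 87 +
6 × 68 = 1191 tests at full scale); per-subcase scope is a flag. Results
are reported at two tiers, q < 0.01 and q < 0.001.

**Confound handling.** Age, gender and total gray-matter volume are
removed by per-region ordinary least squares with an intercept, separately
within each group. A design question is whether permutations should
shuffle pre-computed residual rows (fast) or re-fit the regression inside
every pseudo-group (strict). Calibration simulations on effect-free
cohorts (reproduced in the test suite) showed the fast variant to be
measurably anti-conservative — mixing rows residualized under two
different group fits inflates the observed statistic relative to its
null — while the strict variant is well calibrated. The package therefore
defaults to `refit_confounds = TRUE` and keeps the fast path behind the
flag. The re-fit costs one small QR decomposition per pseudo-group and
case, a few percent of total runtime.

## The synthetic cohort generator

`simulate_cohort()` draws three groups — healthy controls and a patient
cohort measured before and after an intervention — under a latent-factor
Gaussian model chosen so every assumption of the analysis is expressible
as a loading pattern:

* **Global factors** (default 4, loading mean 0.5, sd 0.08): shared
  positive-mean factors that make most region pairs correlate positively,
  as empirical structural covariance does.
* **Community blocks** (size 8, half-block stride, loading 1.2):
  overlapping lobe-like communities giving every region strong local
  partners. This is what keeps the thresholded graphs fully connected at
  20% density; dominant-global-factor alternatives leave weak regions
  isolated below the cut.
* **Cross-property coupling** (default 0.75): all properties share a
  common factor component, so cross-property graphs stay density-feasible
  across the sweep. A single scalar is used for all pairs; arbitrary
  per-pair couplings (including negative ones) are not realizable by any
  positive-definite shared-factor construction.
* **Pre/post pairing** (default correlation 0.7): patient factor scores
  before and after the intervention share a per-pair component; covariates
  are carried over with age advanced one year.
* **Confounds**: age ~ Normal(70, 8) truncated to [45, 90] years, gender ~
  Bernoulli(0.5), total gray-matter volume ~ Normal(6e5, 6e4) mm^3, with
  per-property linear effects only if `confound_betas` is supplied.
* **Planted effects** multiply the factor loadings of a region set in one
  group; for a property pair only the shared component is multiplied,
  planting a cross-property coupling change.

One global seed expands into named substreams (loadings, confounds,
factors, noise) so enlarging one block does not perturb the others, and
`population_correlation()` returns the analytic correlation structure the
empirical matrices converge to — the moment-convergence oracle used in the
tests.

Default group sizes are 29 controls and 34 patients, 68 cortical plus 19
non-cortical parcels, matching the cohort structure of the motivating
study design. Values are written on familiar per-property scales (mm for
CT, mm^2 for SA, mm^3 for volume); correlations are scale-invariant, so
these affect only readability of the files.

**What the generator does not emulate.** Gaussian noise only (no
heavy-tailed segmentation failures); hub structure — real cortex
concentrates degree in association hubs, whereas the community design
spreads degree evenly; spatial autocorrelation beyond the block structure;
and site or scanner effects. Passing tests therefore demonstrate
correctness of the machinery under the stated statistical structure, not
robustness to every artifact of real morphometry.

## Known limitations

* A multiplicative loading boost saturates: scaling a region's loadings by
  m multiplies its covariances by m but also inflates its variance by m^2,
  so the correlation gain is bounded by the region's noise share
  (at m = 1.8 the per-edge gain cannot exceed roughly 0.12 for realistic
  signal shares). With ~34 subjects per group, permutation tests on AUC
  statistics consequently have modest power against such plants; recovery
  experiments at that effect size show planted regions ranking first but
  rarely clearing q-based significance. Detecting subtle covariance
  reorganization at these sample sizes genuinely requires either larger
  cohorts or stronger planted mechanisms, and the package reports this
  honestly rather than overstating sensitivity.
* Structural covariance yields one graph per group; no subject-level
  network statistics (and hence no correlation of graph metrics with
  clinical scores) are possible by construction.
* The clinical-summary t helper reports the correct pooled-variance
  degrees of freedom, `n1 + n2 - 2`; published tables occasionally print a
  different df for unequal group sizes (e.g. 66 where 29 + 34 subjects
  imply 61), which the helper deliberately does not reproduce.

## Problem sizes used in the shipped checks

The test suite and the acceptance script scale the expensive experiments
to: calibration on 20-region cohorts (100 simulations, 200 permutations),
recovery on 30-region cohorts (20 replicates, 1000 permutations), and a
full-scale 87-region, 15-subcase, two-contrast run at 500 permutations —
sizes chosen so the whole suite completes on a single CPU in well under
half an hour while leaving every statistical conclusion unchanged at the
full 8000 permutations, which remains the supported analysis
configuration.
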