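---
title: "Structure-function coupling in parcellated connectomes: methods and design notes"
author: "scfcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfcoupling)
```

## The problem

In a parcellated brain, each region has two connectivity profiles: a
structural one (anatomical connection weights to every other region,
typically tractography-derived streamline weights) and a functional one
(Fisher-z correlations between regional activity time series).
Structure-function (SC-FC) coupling asks how tightly these two profiles
agree, region by region. The package implements the full analysis stack
around that statistic: coupling maps, macroscale gradients of cortical
organisation, spatially constrained permutation inference, covariate-adjusted
group comparison, and association of coupling-difference maps with regional
gene expression — plus a synthetic cohort generator that plants known ground
truth so every stage can be validated without access to imaging data.

## The coupling statistic

For node $i$, take its structural profile $s_i$ and functional profile $f_i$
(both of length $n-1$, the self-entry excluded), restrict both to the indices
where the *structural* entry is nonzero, and compute the Spearman rank
correlation (average-rank ties). Two conventions matter:

* **Support definition.** Structure defines the support. After functional
  matrices are masked to the structural support (`maskFunctionalBySC`, which
  discards functional connections with no anatomical backing), the two
  supports coincide except for exact-zero functional values, which are
  retained as data — whether an empirical pipeline would drop them is not
  decidable from the method description, so the more conservative choice
  (keep) is used.
* **Validity, not zero.** A node with fewer than `minNonzero` (default 3,
  the minimum for a non-degenerate rank correlation) surviving entries, or a
  constant restricted profile, is *invalid*: `NA` with a `FALSE` mask, never
  silently 0. Group maps require validity in at least 50% of subjects.

Global coupling is the arithmetic mean over valid nodes; group comparisons
of it use the same GLM as the nodewise analysis.

## Functional connectome construction

`fcFromTimeseries` computes pairwise Pearson correlations of regional time
series and applies the Fisher transform, clamping $r$ to
$\pm(1 - 10^{-12})$ first so degenerate perfectly correlated rows stay
finite. Pearson is the default because that is the canonical construction;
Spearman is exposed as an option (`method = "spearman"`) since both appear
in the literature on otherwise identical pipelines. Confound regression
(motion, tissue signals) is out of scope: the function consumes cleaned
signals, as those steps belong to dedicated preprocessing tools. No
threshold is applied to FC beyond the structural-support mask, and negative
values are retained.

## Gradients

Connectivity gradients are extracted with the standard diffusion-map
recipe:

1. **Normalized-angle affinity.** Per row, keep the top `rowSparsity`
   fraction of entries (default 0.1 — the convention of the widely used
   gradient toolboxes; the method description itself leaves sparsification
   unstated). Then $A(i,j) = 1 - \arccos(\mathrm{cossim}(x_i, x_j))/\pi$,
   mapping identical profiles to 1, orthogonal to 0.5, anti-parallel to 0.
2. **Diffusion map.** Density-normalize by degree to power $\alpha$
   (default 0.5, anisotropic diffusion), row-normalize to a Markov
   operator, eigendecompose via the conjugate symmetric matrix, drop the
   trivial constant eigenvector, and scale the rest by
   $\lambda/(1-\lambda)$ (the automatic multi-scale weighting selected by
   `diffusionTime = 0`) or $\lambda^t$ otherwise. These defaults mirror the
   cited toolbox conventions, since the method description fixes neither.
   Variance explained per gradient is its eigenvalue over the sum of all
   non-trivial positive eigenvalues; the total is stored on the object so
   the ratio identity can be verified.
3. **Template and alignment.** A group template is embedded from the
   element-wise mean matrix; individuals are aligned to it by orthogonal
   Procrustes (rotation/reflection only — no scaling, no translation, one
   pass against the fixed template rather than iterative re-templating,
   which matches the description "align each individual to the group
   template"). Eigenvalues are carried through alignment unchanged.
4. **Orientation.** Eigenvector sign is arbitrary, so a deterministic
   post-hoc step fixes the reporting convention: gradient 1 is flipped to
   correlate negatively with the anatomical y (A-P) coordinate (higher
   score = more posterior), gradient 2 to correlate positively with
   hierarchy level. Orientation never changes any correlation magnitude.

Ten components are computed by default; analyses focus on the first two.

## Spin permutation inference

Map-map correlations across regions cannot be tested against an i.i.d.
null because cortical maps are spatially autocorrelated. The spin test
builds a null by rigid rotation: draw a uniform random 3-D rotation
(orthonormalized Gaussian triple, determinant +1), rotate the
left-hemisphere sphere centroids, mirror the rotation across the sagittal
plane for the right hemisphere, and reassign each original parcel to its
nearest rotated centroid within its hemisphere. Duplicates are permitted —
the standard parcel-level adaptation. The analysis map is permuted; the
axis/reference map stays fixed.

P-values use the permutation-inclusive (add-one) rule
$p = (\#\{\text{null} \ge \text{emp}\} + 1)/(n_{perm}+1)$, mirrored for the
lower tail and doubled-min (capped at 1) for two-sided. Add-one avoids
$p = 0$ and is conservative by at most $1/(n_{perm}+1)$; the raw proportion
is available (`addOne = FALSE`) for strict replication of descriptions that
state the bare proportion. Two-sided is the default alternative: a purely
one-sided "greater" rule would assign $p \approx 1$ to strong *negative*
correlations, which is clearly not what directional empirical reports
intend, so both tails are implemented and the symmetric default chosen.

Known limitation: nearest-centroid reassignment with duplicates makes
parcel-level spins mildly anticonservative in the literature and here —
calibration on independent isotropic smooth fields in this package's tests
lands near, occasionally slightly above, the nominal level. Variogram-based
generative nulls would avoid this but are out of scope.

## Group inference

Nodewise comparison is mass-univariate OLS of the per-subject map value on
[intercept, group indicator, age, sex], with a two-sided t-test on the
group coefficient (the description reports directional results but states
no sidedness; two-sided is the safe default) and Benjamini-Hochberg FDR
across valid nodes. The group indicator is 1 for the first contrast member,
so `beta_group` is "test minus reference" — a disease-vs-control contrast
yields negative betas for decoupling. Nodes invalid in more than half the
subjects are excluded listwise and reported with `NA`. With no covariates
and balanced groups the GLM reduces exactly to the pooled-variance
two-sample t-test (verified to 1e-10 in tests). BH is `stats::p.adjust`;
the test suite checks it against an exhaustive step-up oracle.
Coupling-behaviour correlation across subjects defaults to Spearman
(consistent with the rank statistics used elsewhere), with Pearson exposed.

## Gene association

The coupling-difference map is the covariate-adjusted group coefficient
per node. Each gene's regional expression column is correlated with it
(Spearman), BH-corrected across genes, and additionally spin-tested by
permuting the difference map. A gene is flagged only when both
$q < 0.05$ and $p_{spin} < 0.05$ — the conjunction reading; whether the
empirical analyses used the spin as a gate or as a reported check is
ambiguous, so the stricter conjunction is the default and is relaxable
(`requireSpin = FALSE`). Note the parametric Spearman p-values that feed
BH assume independent observations and are anticonservative for smooth
maps; the spin component of the conjunction is what actually carries the
spatial null. A constant expression column is skipped with a warning;
other genes are unaffected.

## The synthetic cohort generator

The generator defines the study conditions; it is designed so that every
downstream claim the tests make is a parameter-recovery statement.

* **Geometry.** Nodes are placed on each unit hemisphere by a
  deterministic Fibonacci lattice; the right hemisphere mirrors the left.
  Anatomical centroids scale the sphere onto an ellipsoid with semi-axes
  (55, 70, 50) mm — the A-P axis longest, as in real cortex — giving a
  monotone A-P (y) coordinate for axis correlations. Seven latitude bands
  serve as networks, mapped onto hierarchy levels 1-4 in the canonical
  sensory-to-transmodal order. Latitude bands are a simplification; the
  only property downstream code uses is a spatially contiguous
  node-to-level map.
* **Structural graph.** Edges are sampled with probability proportional to
  $\exp(-\text{decay} \cdot d)$ where $d$ is distance in a metric
  stretched 3x along A-P, calibrated to hit the target density within
  0.02. The stretch makes the cortex effectively elongated
  anterior-posteriorly, so the leading diffusion gradient of the synthetic
  connectome tracks the A-P axis — on an isotropic sphere no axis would be
  preferred and gradient-axis recovery would be undefined. Default density
  is 0.6: unthresholded streamline-weighted structural matrices are dense,
  and the planted-coupling recovery contract presumes at least ~50
  neighbours per node. Weights are log-normal.
* **Planted coupling.** The target field is
  $\kappa_i = \beta_0 + \beta_{AP} \cdot y_i/70 + \beta_{hier} \cdot (L_i - 2.5)$
  plus group-specific additive deltas, clipped to $[-0.99, 0.99]$.
  Subject FC profiles are drawn through a Gaussian copula: node $i$'s
  latent profile is $\rho_i z + \sqrt{1-\rho_i^2}\,\varepsilon$ with $z$
  the normal scores of the (noisy) SC profile and
  $\rho_i = 2\sin(\pi \kappa_i / 6)$ — the inverse of the bivariate-normal
  Pearson-to-Spearman relation $\rho_S = (6/\pi)\arcsin(\rho/2)$ — so the
  expected Spearman coupling equals $\kappa_i$ before symmetrization.
  Averaging the two endpoint draws per edge then *perturbs* realized
  coupling: shared signal survives the average while independent noise
  cancels, inflating coupling where neighbouring $\kappa$ is high and
  attenuating it where it is low. The defaults
  ($\beta_0 = 0.415$, $\beta_{AP} = -0.16$, $\beta_{hier} = -0.06$,
  noise 0.1) were calibrated once by simulation so a 20-subject control
  cohort's mean global coupling lands at 0.54, the healthy-control level
  in this literature, with per-node values spanning roughly 0.2-0.8 —
  comparable to empirical per-subject ranges.
* **Expression maps.** Gene maps are Gaussian-kernel-smoothed white noise
  on the sphere (bandwidth 0.2 rad by default — chosen so that null genes
  correlate with an independent target map below |rho| = 0.2 in at least
  90% of draws at 400 nodes, the generator's stated contract), mixed with
  the normal scores of a target map via a root-solved weight to hit a
  requested Spearman within 0.1, then passed through an outlier-robust
  sigmoid into (0,1). The sigmoid is strictly monotone, so all rank
  statistics are unaffected by it. Fields are isotropic on the sphere,
  which makes the spin null exact for them up to parcellation effects.
* **Demographics.** Ages are Normal(66.8, 9.3), sex a fair coin — the
  profile of the elderly cohorts this analysis targets.
* **Determinism.** Every generator is a pure function of (arguments,
  seed); pipeline stages derive their seeds from the master seed by a
  stable polynomial hash of the stage name, so toggling one stage never
  reshuffles another's randomness.

**What the generator does not emulate:** biophysical BOLD dynamics,
tractography biases (false positives/negatives, gyral bias), realistic
cortical geometry or folded topology, distance-dependent functional
coupling beyond what the structural support induces, hemispheric
specialisation, or subject-level covariate effects on coupling (age and
sex are noise covariates, not planted effects). Passing tests therefore
demonstrate that the *statistical machinery* recovers known truth under a
clean generative model — not that the pipeline is robust to the
acquisition artefacts of real imaging data.

## Numerical choices

* Matrix loaders average sub-1e-8 asymmetries (text round-trip noise) and
  reject anything larger; the diagonal is forced to zero.
* Correlations are clamped before `atanh`; cosine similarities before
  `arccos`.
* Eigenvalues are clipped below 1 before the $\lambda/(1-\lambda)$
  scaling to guard against numerically degenerate (near-disconnected)
  affinities.
* Nearest-centroid assignment breaks exact ties by lowest index,
  keeping permutations reproducible across platforms.
* Sign orientation with an exactly zero axis correlation leaves the sign
  as computed and warns.
* Parametric correlation p-values that underflow to 0 at perfect
  correlations are floored at the smallest positive double before BH.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's validation conditions: 100-node parcellations (400 nodes for
the gene-association and expression-contract checks), 10-20 subjects per
group, 1000 spin rotations for inference (a few hundred where only
determinism or counting rules are under test), 50-run simulation batches
for power/FDR properties, and 200 field pairs for spin calibration. At
these sizes the full suite completes in minutes on one core.
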