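# scfcoupling

Structure–function coupling analysis for parcellated brain connectomes.

## What this package is for

Each region of a parcellated brain has two connectivity profiles: a
*structural* profile (anatomical connection weights to all other regions,
e.g. tractography streamline weights) and a *functional* profile (Fisher-z
correlations between regional activity time series). How tightly the two
agree — per region — is **SC–FC coupling**:

> κ(i) = Spearman( s_i, f_i ) over the nonzero entries of the structural
> profile,

a rank statistic in [−1, 1] per node. Cohort studies in network
neuroscience use it to ask where structure and function decouple in
disease, whether decoupling follows macroscale cortical gradients, and
which neuromodulatory systems' regional gene expression it tracks.

The package implements that full stack, for analysts working with
parcellated connectivity matrices (delimited text; no neuroimaging-format
I/O):

* **Coupling** — per-node, per-subject maps; global means; group means
  with explicit validity masks (`couplingMap`, `globalCoupling`,
  `groupMeanMap`).
* **FC construction** — Fisher-z Pearson (or Spearman) matrices from
  regional time series, and masking of functional edges without
  structural support (`fcFromTimeseries`, `maskFunctionalBySC`).
* **Gradients** — normalized-angle affinity
  A(i,j) = 1 − arccos(cos sim(x_i, x_j))/π, diffusion map embedding,
  group templates, orthogonal Procrustes alignment, deterministic sign
  orientation, and gradient–axis correlations
  (`normalizedAngleAffinity`, `diffusionMapEmbed`, `buildGroupTemplate`,
  `procrustesAlign`, `orientGradients`, `axisCorrelation`).
* **Spatial inference** — parcel-level spin permutations (random 3-D
  rotations, hemisphere-mirrored, nearest-centroid reassignment) with
  add-one permutation p-values (`generateSpinPermutations`, `spinTest`).
* **Group inference** — nodewise GLM with age/sex covariates,
  Benjamini–Hochberg FDR, global comparisons, coupling–behaviour
  correlation (`nodewiseGLM`, `fdrBH`, `globalComparison`,
  `couplingScoreCorrelation`).
* **Gene association** — Spearman correlation of a covariate-adjusted
  coupling-difference map with regional gene-expression columns, FDR
  across genes plus a spin-test conjunction (`deltaCouplingMap`,
  `geneMapCorrelation`).
* **Synthetic cohorts** — a generator that plants known coupling fields
  (via a Gaussian copula with exact Spearman targets), group decoupling
  effects, and spatially autocorrelated expression maps, so the whole
  pipeline is testable end to end (`makeCohort`, `makeExpressionTable`).

Central data structures are S4 classes with validity checks:
`Parcellation`, `ConnectivityMatrix`, `CouplingMap`, `GradientSet`,
`SpinNull`, plus `CohortDesign`/`CouplingField` for simulation.

## Worked example

The one-call demo runs the whole pipeline on a synthetic three-group
cohort (healthy-control analogue plus two progressively decoupled disease
groups, with 8 focally decoupled nodes planted in the low-performing
group and one gene planted to track the group difference map):

```r
library(scfcoupling)
res <- runPipeline(defaultRunConfig(42))
cat(res$report, sep = "\n")
```

```
scfcoupling pipeline report
master seed: 42

simulate: 100 nodes, groups [control n=10, pd_high n=10, pd_low n=10]

global SC-FC coupling (cohort means):
  control: 0.536
  pd_high: 0.480
  pd_low: 0.444

structural template gradients:
  variance explained: g1 3.6%, g2 2.7%
  gradient 1 vs A-P axis: rho = -0.912, p_spin = 0.003996
  gradient 2 vs hierarchy: rho = 0.091, p_spin = 0.4955

group comparisons:
  pd_high vs control: global diff -0.059 (p = 6.68e-08); 4/100 nodes significant at q < 0.05
  pd_low vs pd_high: global diff -0.038 (p = 1.26e-05); 4/100 nodes significant at q < 0.05

gene association (pd_high vs control): 2/10 genes significant (DRD2, null_gene_08)
```

Reading it: the control cohort mean global coupling sits at its calibrated
healthy-control level (~0.54); the two disease groups show the planted
global decoupling (−0.06 and −0.075 planted; −0.059 recovered for the
first contrast, covariate-adjusted); the leading structural gradient
tracks the anterior–posterior axis (rho = −0.91 against the y coordinate,
spin-test p < 0.05); the focal contrast flags a subset of the 8 planted
nodes at q < 0.05; and the gene screen recovers the planted `DRD2`
association (rho target −0.4) — with, in this particular run, one of the
nine null genes false-flagged, the kind of borderline event a 5%
two-filter screen permits. `runPipeline(cfg, outDir = "out/")` writes all
per-node tables (TSV), a JSON manifest with the config hash and seed, and
this report. A YAML config (`loadRunConfig`) and a thin CLI
(`inst/cli/scfc.R`, subcommands `simulate`, `build-fc`, `couple`,
`gradients`, `spin`, `compare`, `genes`, `run`) expose the same pipeline
from the shell.

## Scope notes

Imaging preprocessing (tractography, fMRI cleaning) and donor-level
transcriptomic processing are out of scope: the package consumes
parcellated matrices, cleaned signal tables, and a finished
region × gene expression table. See the methods vignette
(`vignettes/scfc-methods.Rmd`) for the model details, parameter
rationale, numerical choices, and known limitations.
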