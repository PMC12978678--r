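---
title: "Multivariate lesion-symptom mapping: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate lesion-symptom mapping: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemap)
```

## The problem

After a left-hemisphere stroke, reading deficits (alexia) dissociate into
lexical impairments (reading known words) and sublexical impairments
(decoding unfamiliar letter strings via learned orthography-to-phonology
mappings). Lesion-symptom mapping asks which damaged voxels — or which lost
white-matter connections — predict a specific behavioral deficit across a
patient cohort, while controlling for nuisance variables and for related
behaviors so that the mapped deficit is as process-specific as possible.

`strokemap` implements this analysis at two levels with one shared engine:

* **SVR-VLSM** (`svr_vlsm()`): patients x voxels binary lesion matrix,
  clusterwise permutation inference on the back-projected SVR beta map.
* **SVR-CLSM** (`svr_clsm()`): patients x edges binary disconnection matrix
  derived from structural connectomes, single-step maxT permutation
  inference at the edge level plus an aggregated parcel level.

## The model

For one contrast, let `y` be the pooled accuracy on the target stimulus
classes (e.g. all pseudowords) and `C` the covariate block: the behavioral
control accuracies of the contrast (e.g. real words) together with lesion
volume, age, and education. Both `y` and every feature column (voxel or
edge) are replaced by their least-squares residuals on `[1, C]`
(`residualize()`); behavioral and nuisance covariates are deliberately one
block — the analysis treats "controlling for" identically wherever it comes
from.

An epsilon-SVR is then fitted to the residualized data and its weight
vector back-projected to features. With the linear kernel (default) the
beta map is exactly `t(X) %*% (alpha - alpha*)`, the primal weights. Two
implementation details matter:

* The fit is computed on an `n x n` factor `Z` of the Gram matrix
  (`Z Z' = X X'`): the dual problem is identical, but each of the thousands
  of permutation refits costs `O(n^3)` instead of `O(n^2 k)`. We verified
  the factorized fit reproduces the direct fit to ~1e-15.
* `X` is divided by one global constant (the root-mean-square subject
  vector norm) so that `C` and `epsilon` mean the same thing for any grid
  or cohort size. Columns are never individually rescaled: a rarely
  lesioned voxel should contribute less, and that information lives in the
  column scale.

The dependent variable is standardized to unit variance after
residualization (`standardize_y = TRUE`).

Damage is coded 1 and higher scores mean better performance, so a
deleterious feature acquires a *negative* beta; all inference is one-tailed
negative.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `kernel` | linear | exact, oracle-checkable back-projection; `rbf` available with dual-coefficient (sensitivity-style) back-projection |
| `C` | 0.3 | SVR cost. Set by power calibration on seeded synthetic cohorts: at desk scale, strong regularization prevents the permuted-label refits from absorbing noise, which is what gives the per-feature permutation test its sensitivity. Familywise error control holds for any `C` because the null is permutation-derived; `C` moves power only. |
| `epsilon` | 0.1 | insensitivity tube on the standardized dependent variable |
| `standardize_y` | TRUE | unit-variance y after residualization |

## Permutation inference

`permutation_null()` shuffles the residualized `y` (permutation `b` uses
seed `scheme$seed + b`) and refits; covariates are already out of both
sides, so the labels are exchangeable under the null. Featurewise p-values
use the add-one rank formula `p_j = (1 + #{beta_j^(b) <= beta_j^obs}) /
(n_perm + 1)`, which cannot reach 0.

**Clusterwise correction (voxels).** Suprathreshold voxels
(`p < voxel_forming_p`, default 0.005) are grouped into connected
components (connectivity 26 by default; 6 and 18 available) and each
observed cluster's voxel count is referred to the permutation distribution
of the *maximum* cluster size. Each permutation's own suprathreshold map is
obtained by ranking that permutation's beta within its feature column
across all permutations (ties toward the larger rank, divided by
`n_perm`) — the permutation analogue of the observed p-map. Cluster mass is
the voxel count because the field reports "cluster size"; centers of mass
are unweighted means of voxel centers through the affine.

**maxT correction (edges).** Connectome space has no spatial clusters, so
edges use single-step maxT: the null statistic of permutation `b` is
`min_e beta_e^(b)` and `p_fwer_j = (1 + #{min beta^(b) <= beta_j^obs}) /
(n_perm + 1)`.

**Parcel level.** The parcel statistic is the sum of negative parts of the
edge betas over the parcel's retained incident edges, referred to the
per-permutation maximum of the same statistic across parcels, reusing the
identical permutation stream. The aggregation choice is ours — parcel-level
evaluation is part of the design, but no standard statistic exists;
alternatives (minimum incident edge p, count of suprathreshold edges) would
slot into the same null machinery. Parcels with no retained incident edge
are reported "not analyzable" rather than null-accepted.

## Filters and the disconnectome

* Voxels enter the design when lesioned in **at least 10%** of patients
  (inclusive `>=`).
* Edges enter when disconnected in **strictly more than 10%** of patients —
  the two conventions differ on purpose, mirroring the differing wording
  of the respective rules ("at least" vs "greater than").
* An edge is *analyzable* only if present (weight > 0) in **100% of
  controls**; `binarize_disconnection()` marks an analyzable edge
  disconnected when the patient weight is exactly 0 (below `tol = 1e-12`
  for float inputs). Cross-sectional-area edge weights make absence a
  meaningful zero.

## The synthetic cohort generator

`simulate_cohort()` creates the whole study object deterministically from
one seed: a mirrored Voronoi toy atlas with straight-line tract
trajectories (`make_atlas()`), compact left-hemisphere lesions grown to
lognormal target volumes (`simulate_lesions()`), control and patient
connectomes in which a lesion crossing a trajectory zeroes the edge
(`simulate_connectomes()`), and binomial reading accuracies whose logit
depends on covariates and on damage to seeded critical structures
(`simulate_behavior()`), with the ground truth exported.

Default conditions and their rationale:

* **Grid 20x24x20 at 2 mm, 4 parcels per hemisphere.** Large enough for
  clusters to form and for 10 tract trajectories, small enough that a
  full 500-permutation analysis runs in seconds — the scale at which
  hundred-replicate error-rate studies are feasible on one CPU.
* **64 patients, 71 controls;** ages ~N(61.6, 11.6) truncated to [39, 92]
  for patients (controls N(61.6, 11.5) on [31, 83]); education ~N(16.5,
  2.8) on [9, 21] (controls N(17.2, 2.5) on [12, 21]) — the demographic
  profile of a chronic left-hemisphere stroke cohort with matched
  controls.
* **Lesion volumes** lognormal(meanlog 5.93, sdlog 0.75) in voxels: mean
  ~500 of 4,800 left-hemisphere voxels, i.e. the same ~15% hemispheric
  fraction and ~0.87 coefficient of variation that a 90 cm^3-mean,
  78 cm^3-SD lesion distribution occupies in a real hemisphere. Growth is
  compact (frontier candidates are scored by how many lesioned neighbors
  they already have) because infarcts are blob-like; dendritic lesions
  would give neighboring voxels artificially decorrelated lesion columns.
* **Behavior**: baseline logits reproduce typical control accuracies (real
  words 94.3%, 0M 89.7%, 1M 94.3%, MM 93.2%); 200 real-word trials and 20
  per pseudoword class; per-SD covariate effects (education +0.45, age
  -0.13) on the scale of observed demographic effects; item durations
  lognormal, capped at the 10 s timeout. Durations feed only the
  behavior-level utilities (`inverse_duration()`), not the LSM dependent
  variables, mirroring the control-only duration analysis.
* **Connectomes**: edge weight `10 * (1 + U(-0.2, 0.2))`; 10% of edges are
  designated unreliable and dropped from a random 30% of controls, so the
  100%-presence filter always has something to do.
* **Effects**: `region_effect` wires a *graded* deficit to the lesioned
  fraction of a contiguous critical region (giving VLSM a recoverable
  gradient); `edge_effect` wires a *binary* deficit to disconnection of
  one critical edge — the reliable edge whose cut fraction is nearest 1/2,
  i.e. the maximal-variance, hence detectable, wiring. Weights apply to the
  pseudoword classes only, so the lexicality contrast is the sensitive one.
  The generative logit model is a validation construct: the real study
  fits descriptive models and prescribes no generative behavioral model.

What the generator does *not* emulate: vascular lesion anatomy, curved
tracts and genuine tractography failure modes, item-level psycholinguistic
structure, spatial correlation of behavioral noise. Passing recovery and
error-rate tests therefore demonstrates that the *pipeline machinery* is
correct and calibrated under the assumed generating model, not that the
method is unconditionally valid on real imaging data.

## Numerical and degenerate-input conventions

* Mask loading binarizes at > 0.5 (interpolated masks carry fractions).
* Connectome asymmetry <= 1e-6 is averaged away, more is an error; nonzero
  diagonals are zeroed with a warning.
* Residual orthogonality is guaranteed to 1e-8 (QR); rank-deficient
  covariates raise a collinearity error naming the dependent columns.
* A constant (all-inside-the-tube) dependent variable yields a zero beta
  map, not an error.
* No suprathreshold voxels is an empty, logged result, not an error.
* p-kind stat maps carry the sentinel 0 outside lesion coverage.
* Cohorts below 10 retained patients refuse to fit.
* All seeds are explicit; identical config + seed reproduces every output
  byte for byte.

## Validation summary

The test suite regenerates everything it checks:

* exact oracle equivalence of the combinatorial pieces (disconnectome rule
  vs a triple loop, coverage/edge filters vs direct counting, cluster
  labeling vs an igraph flood fill, linear betas vs least squares on
  well-conditioned designs);
* empirical familywise error of both pipelines on 100 null cohorts
  (n = 64, 500 permutations) bounded by the nominal 0.05 plus two binomial
  standard errors;
* recovery of a seeded 100-voxel critical region (logit effect -4) and of
  a seeded critical edge in at least 80% of 20 replicate cohorts;
* bitwise determinism of written maps, tables, and summaries.

Problem sizes in the suite (100 + 20 + 20 cohorts, 500 permutations each)
are the package's chosen desk-scale study conditions; study-scale runs
(10,000 permutations) use the same code paths.

## Known limitations

* The rbf back-projection is a sensitivity-style approximation, not a
  primal weight vector; linear is the supported inferential default.
* Freedman-Lane-style permutation of residualized labels is approximate in
  finite samples; the error-rate simulations are the check that the
  approximation is adequate at this scale.
* The parcel statistic is one defensible choice among several; parcel
  p-values should be read as a summary of incident-edge evidence, not as
  an independent test family.
* Lesion volume is computed from the supplied common-space masks; whether
  a native-space volume would serve better is a data question the package
  cannot settle.
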