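# strokemap

Multivariate lesion-symptom mapping for stroke cohorts with support vector
regression, at the voxel level (SVR-VLSM) and the structural-connectome
level (SVR-CLSM), plus a fully seeded synthetic cohort generator for
validating every stage without imaging data.

## What problem this solves

Lesion-symptom mapping relates where a stroke damaged the brain to *which*
behavior it impaired, across a patient cohort. Mass-univariate approaches
test each voxel alone; the multivariate SVR approach instead fits one model
of behavior on all lesion features jointly and interrogates its
back-projected weight map, which respects the strong spatial correlation of
lesions. The connectome variant replaces voxels with *disconnections*:
white-matter edges that a patient lost but every control possesses, so that
spared-but-disconnected regions are credited too. Typical users are
aphasia/alexia researchers mapping deficits such as an exaggerated
lexicality effect (pseudoword reading worse than real-word reading —
phonological alexia) onto perisylvian lesions and frontoparietal
disconnections.

## The model

For a contrast with dependent accuracy `y` (a stimulus-class union) and
covariate block `C` (behavioral control accuracies + lesion volume, age,
education), with lesion/edge matrix `X ∈ {0,1}^{n×k}`:

1. **Residualize both sides**: `X* = (I − P_[1,C]) X`, `y* = (I − P_[1,C]) y`.
2. **Fit epsilon-SVR** of `y*` on `X*` (linear kernel default, C = 0.3,
   ε = 0.1, y standardized) and back-project the beta map
   `β = X*ᵀ(α − α*)` — the exact primal weights for the linear kernel.
3. **Permutation inference**, one-tailed negative (damage coded 1, higher
   `y` better): permutation `b` refits on shuffled `y*`;
   `p_j = (1 + #{β_j^{(b)} ≤ β_j^{obs}}) / (B + 1)`.
4. **Familywise error control**: voxel maps form clusters at p < 0.005
   (26-connectivity) and compare observed cluster sizes with the null
   maximum cluster size; edges use single-step maxT on `min_e β^{(b)}`;
   parcels aggregate incident-edge negative beta mass against a max-parcel
   null.

Design filters: voxels lesioned in **≥ 10%** of patients; edges
disconnected in **> 10%** of patients and present in **100% of controls**.

## Worked example

Simulate a 64-patient cohort in which damage to a seeded 100-voxel
critical region shifts pseudoword (but not real-word) accuracy by up to −4
logits, then map the deficit:

```r
library(strokemap)

sc  <- simulate_cohort(seed = 42, region_effect = 4)
fit <- svr_vlsm(sc$masks, sc$cohort, "pseudoword_lexicality",
                scheme = perm_scheme(n_perm = 1000, seed = 42))
fit
#> SVR-VLSM: contrast 'pseudoword_lexicality', 64 patients, 1528 voxels (coverage >= 0.10)
#>   1000 permutations, voxel-forming p < 0.005, clusterwise FWER alpha = 0.05, connectivity 26
#>   2 cluster(s), 1 significant
#>   cluster size_cm3  center_of_mass   p_cluster significant
#> 1       2    1.128 6.7, 17.6, 22.6 0.000999001        TRUE
#> 2       1    0.008  8.0, 4.0, 16.0 0.915084915       FALSE
```

One cluster survives clusterwise FWER (p ≈ 0.001): 141 voxels (1.128 cm³)
whose center of mass sits in the simulated "perisylvian" territory. It is
the seeded region:

```r
det <- which(fit$cluster_map$values > 0)
recovery_metrics(det, sc$truth$critical_voxels, dim = sc$atlas$shape)
#> $dice              0.49
#> $centroid_distance 1.08   # voxels
#> $hit               TRUE
```

The connectome variant on a cohort with a seeded critical *edge* flags
exactly that edge and its two endpoint parcels:

```r
sce <- simulate_cohort(seed = 42, edge_effect = 4)
cfit <- svr_clsm(sce$connectomes$patients, sce$connectomes$controls,
                 sce$cohort, "pseudoword_lexicality",
                 scheme = perm_scheme(n_perm = 1000, seed = 42))
cfit
#> SVR-CLSM: contrast 'pseudoword_lexicality', 64 patients, 8 edges (disconnection > 0.10)
#>   1000 permutations, single-step maxT FWER alpha = 0.05, one-tailed negative
#>   significant edges: 1 / 8; significant parcels: 2 / 7 analyzable
#>  parcel_a parcel_b      beta      p_fwer
#>        L3       L4 -2.177266 0.000999001
```

The five built-in contrasts (`reading_contrasts()`) are
`pseudoword_lexicality`, `realword_lexicality`, `learned_mappings`
(1M+MM | 0M + real words), `multiple_mappings` (MM | 1M + real words), and
`zero_mappings` (0M | 1M+MM + real words). Real cohorts enter through
`read_lesion_masks()`, `read_connectome()`, and `read_cohort_table()`;
results leave through `write_vlsm_results()` / `write_clsm_results()`
(NIfTI maps, TSV tables, JSON summaries).

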