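Package: strokemap
Title: Multivariate Lesion-Symptom Mapping with Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxel-based and connectome-based multivariate lesion-symptom
    mapping for stroke cohorts using support vector regression (SVR-VLSM and
    SVR-CLSM). Provides nuisance-covariate residualization of lesion and
    behavioral data, linear-kernel SVR with exact beta-map back-projection,
    permutation-based familywise error control (clusterwise for voxel maps,
    single-step maxT for connectome edges and parcels), construction of binary
    structural disconnectomes from weighted connectomes, built-in
    covariate-controlled oral-reading contrasts, and a fully seeded synthetic
    stroke-cohort generator (toy atlas, lesions, connectomes, behavior) with
    exported ground truth for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
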