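# Synthetic stroke-cohort generator: toy atlas, left-lateralized lesions,
# structural connectomes with lesion-induced disconnections, and binomial
# reading behavior with exported ground truth. Every stage is seeded and
# bitwise reproducible, so the full analysis pipeline can be validated
# without any imaging data.

#' Build a toy two-hemisphere atlas
#'
#' Seeded-Voronoi parcels on the left half of the grid (farthest-point
#' seeding, nearest-seed assignment) mirrored onto the right half, with
#' discrete straight-line tract trajectories between all pairs of left
#' parcel centroids and between homotopic left/right pairs. A miniature
#' stand-in for a whole-brain parcellation: K=4 gives 8 parcels with
#' choose(4,2)=6 intrahemispheric plus 4 homotopic trajectories.
#'
#' @param shape integer grid dimensions, each >= 12.
#' @param K number of left-hemisphere parcels (>= 4).
#' @param seed integer seed.
#' @return Object of class `toy_atlas`: `labels` (3D integer array, parcels
#'   1..2K), `parcel_names` (`L1..LK`, `R1..RK`), `centroids` (2K x 3,
#'   1-based voxel indices), `edges` (data frame `parcel_a`, `parcel_b`),
#'   `trajectories` (list of linear voxel index vectors, one per edge),
#'   `shape`, `left_max` (largest left-hemisphere x index).
#' @export
make_atlas <- function(shape = c(20L, 24L, 20L), K = 4L, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 12L))
    stopf("atlas grid must be 3D with every axis >= 12")
  K <- as.integer(K)
  left_max <- shape[1] %/% 2L
  n_left <- left_max * shape[2] * shape[3]
  if (K < 4L) stopf("K must be >= 4")
  if (K * 20L > n_left)
    stopf("K = %d parcels infeasible on a %s grid", K,
          paste(shape, collapse = "x"))

  coords <- as.matrix(expand.grid(i = seq_len(left_max), j = seq_len(shape[2]),
                                  k = seq_len(shape[3])))
  seeds <- with_seed(seed, {
    first <- sample.int(nrow(coords), 1L)
    chosen <- first
    for (s in seq_len(K - 1L)) {
      d2 <- rowSums((coords - matrix(coords[chosen[1], ], nrow(coords), 3,
                                     byrow = TRUE))^2)
      for (c2 in chosen[-1])
        d2 <- pmin(d2, rowSums((coords - matrix(coords[c2, ], nrow(coords), 3,
                                                byrow = TRUE))^2))
      chosen <- c(chosen, which.max(d2))
    }
    chosen
  })
  # nearest-seed (Voronoi) assignment of every left voxel
  d2 <- vapply(seeds, function(s)
    rowSums((coords - matrix(coords[s, ], nrow(coords), 3, byrow = TRUE))^2),
    numeric(nrow(coords)))
  assign_left <- max.col(-d2, ties.method = "first")

  labels <- array(0L, shape)
  labels[coords] <- assign_left
  # mirror: right-hemisphere voxel (i,j,k) gets parcel of (shape1+1-i, j, k)
  for (i in seq(left_max + 1L, shape[1])) {
    mi <- shape[1] + 1L - i
    if (mi >= 1L && mi <= left_max)
      labels[i, , ] <- labels[mi, , ] + K
  }

  centroids <- t(vapply(seq_len(2L * K), function(p) {
    ijk <- arrayInd(which(labels == p), shape)
    round(colMeans(ijk))
  }, numeric(3)))

  line_voxels <- function(a, b) {
    nstep <- max(abs(b - a))
    if (nstep == 0L) return(matrix(a, 1))
    t <- seq(0, 1, length.out = nstep + 1L)
    unique(round(cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                       a[3] + t * (b[3] - a[3]))))
  }
  parcel_names <- c(paste0("L", seq_len(K)), paste0("R", seq_len(K)))
  pairs <- rbind(t(utils::combn(seq_len(K), 2L)),            # left intra
                 cbind(seq_len(K), K + seq_len(K)))          # homotopic
  trajectories <- lapply(seq_len(nrow(pairs)), function(e) {
    v <- line_voxels(centroids[pairs[e, 1], ], centroids[pairs[e, 2], ])
    as.integer(v[, 1] + (v[, 2] - 1L) * shape[1] +
               (v[, 3] - 1L) * shape[1] * shape[2])
  })
  structure(list(labels = labels, parcel_names = parcel_names,
                 centroids = centroids,
                 edges = data.frame(parcel_a = parcel_names[pairs[, 1]],
                                    parcel_b = parcel_names[pairs[, 2]]),
                 trajectories = trajectories, shape = shape,
                 left_max = left_max, K = K, seed = as.integer(seed)),
            class = "toy_atlas")
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat(sprintf("<toy_atlas> %s grid, %d parcels (%d per hemisphere), %d tract trajectories\n",
              paste(x$shape, collapse = "x"), 2 * x$K, x$K, nrow(x$edges)))
  invisible(x)
}

# ball of voxels around the left-hemisphere "perisylvian" territory center
.territory_voxels <- function(atlas, radius = 4) {
  ctr <- colMeans(atlas$centroids[seq_len(atlas$K), , drop = FALSE])
  coords <- as.matrix(expand.grid(i = seq_len(atlas$left_max),
                                  j = seq_len(atlas$shape[2]),
                                  k = seq_len(atlas$shape[3])))
  keep <- rowSums((coords - matrix(ctr, nrow(coords), 3, byrow = TRUE))^2) <=
    radius^2
  as.integer(coords[keep, 1] + (coords[keep, 2] - 1L) * atlas$shape[1] +
             (coords[keep, 3] - 1L) * atlas$shape[1] * atlas$shape[2])
}

# grow a 26-connected region of exactly `size` voxels from `start`
# (linear index), restricted to the left hemisphere; assumes RNG is seeded
.grow_region <- function(start, size, atlas) {
  d <- atlas$shape
  off <- .neighbor_offsets(26L)
  seen <- logical(prod(d)) # already in region or frontier
  frontier <- start
  seen[start] <- TRUE
  res <- integer(size)
  count <- 0L
  in_region <- logical(prod(d))
  while (count < size && length(frontier)) {
    # compact growth: among a few random frontier candidates take the one
    # with the most already-lesioned neighbors (infarcts are blob-like, not
    # dendritic); ties broken by candidate order
    ncand <- min(5L, length(frontier))
    cand <- if (length(frontier) == 1L) 1L
            else sample.int(length(frontier), ncand)
    if (count == 0L) {
      pick <- cand[1L]
    } else {
      support <- vapply(frontier[cand], function(fv) {
        fijk <- arrayInd(fv, d)
        fi <- fijk[1] + off[, 1]; fj <- fijk[2] + off[, 2]
        fk <- fijk[3] + off[, 3]
        okn <- fi >= 1 & fi <= d[1] & fj >= 1 & fj <= d[2] &
          fk >= 1 & fk <= d[3]
        sum(in_region[fi[okn] + (fj[okn] - 1L) * d[1] +
                      (fk[okn] - 1L) * d[1] * d[2]])
      }, 0L)
      pick <- cand[which.max(support)]
    }
    v <- frontier[pick]
    frontier[pick] <- frontier[length(frontier)]
    frontier <- frontier[-length(frontier)]
    count <- count + 1L
    res[count] <- v
    in_region[v] <- TRUE
    ijk <- arrayInd(v, d)
    ni <- ijk[1] + off[, 1]; nj <- ijk[2] + off[, 2]; nk <- ijk[3] + off[, 3]
    ok <- ni >= 1 & ni <= atlas$left_max & nj >= 1 & nj <= d[2] &
      nk >= 1 & nk <= d[3]
    lin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
    new <- lin[!seen[lin]]
    seen[new] <- TRUE
    frontier <- c(frontier, new)
  }
  sort(res[seq_len(count)])
}

#' Simulate left-lateralized stroke lesions
#'
#' Each lesion is grown by seeded stochastic region-growing from a random
#' left-hemisphere seed voxel — biased toward a perisylvian territory (a
#' ball around the centroid of the left parcels, the middle-cerebral-artery
#' stand-in) — to a target voxel count drawn from a lognormal distribution.
#' Lesions are single 26-connected components confined to the left
#' hemisphere. Defaults reproduce the hemispheric lesion-load profile of a
#' chronic left-hemisphere stroke cohort (mean ~500 of 4,800 left voxels,
#' coefficient of variation ~0.87) at toy-grid scale.
#'
#' @param n number of patients (>= 10).
#' @param atlas a [make_atlas] object.
#' @param volume_lognormal `c(meanlog, sdlog)` of the voxel-count
#'   distribution.
#' @param territory_bias probability that a lesion seed falls inside the
#'   perisylvian territory (default 0.7).
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @param seed integer seed.
#' @return List of [lesion_mask]; each carries attributes `seed_voxel` and
#'   `territory` (linear indices).
#' @export
simulate_lesions <- function(n, atlas, volume_lognormal = c(5.93, 0.75),
                             territory_bias = 0.7, voxel_mm = 2, seed = 1L) {
  if (n < 10L) stopf("simulate at least 10 patients")
  terr <- .territory_voxels(atlas)
  d <- atlas$shape
  left_lin <- which(array(slice.index(array(0L, d), 1) <= atlas$left_max, d))
  n_left <- length(left_lin)
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  with_seed(seed, {
    sizes <- pmax(1L, round(stats::rlnorm(n, volume_lognormal[1],
                                          volume_lognormal[2])))
    if (any(sizes > n_left)) {
      warnf("%d lesion target volume(s) exceed the hemisphere; clipped",
            sum(sizes > n_left))
      sizes <- pmin(sizes, n_left)
    }
    lapply(seq_len(n), function(i) {
      sv <- if (stats::runif(1) < territory_bias)
        terr[sample.int(length(terr), 1L)]
      else left_lin[sample.int(n_left, 1L)]
      vox <- .grow_region(sv, sizes[i], atlas)
      g <- array(0L, d)
      g[vox] <- 1L
      m <- lesion_mask(g, aff, sprintf("pat%03d", i))
      attr(m, "seed_voxel") <- sv
      attr(m, "territory") <- terr
      m
    })
  })
}

#' Simulate control and patient structural connectomes
#'
#' Control edge weights are `base_weight * (1 + u)`, `u ~ U(-noise, noise)`,
#' for every edge with a tract trajectory in the atlas; a designated
#' fraction of edges is unreliable and zeroed in a random 30% of controls
#' (exercising the present-in-100%-of-controls filter). A patient's edge
#' weight is control-like unless their lesion intersects any voxel of the
#' edge's trajectory, in which case it is exactly 0 — the causal rule the
#' disconnectome construction is designed to detect.
#'
#' @param atlas a [make_atlas] object.
#' @param lesions list of [lesion_mask] on the atlas grid.
#' @param n_controls number of control connectomes (default 71).
#' @param base_weight mean edge weight (cross-sectional-area scale).
#' @param weight_noise relative uniform noise half-width (default 0.2).
#' @param unreliable_edge_fraction fraction of edges unreliably present in
#'   controls (default 0.1).
#' @param unreliable_rate per-control probability that an unreliable edge is
#'   absent (default 0.3).
#' @param seed integer seed.
#' @return List: `controls` and `patients` (lists of [connectome]),
#'   `unreliable_edges` (edge indices), `patient_cut` (list, per patient,
#'   of atlas edge indices zeroed by the lesion).
#' @export
simulate_connectomes <- function(atlas, lesions, n_controls = 71L,
                                 base_weight = 10, weight_noise = 0.2,
                                 unreliable_edge_fraction = 0.1,
                                 unreliable_rate = 0.3, seed = 1L) {
  nE <- nrow(atlas$edges)
  P <- length(atlas$parcel_names)
  ei <- cbind(match(atlas$edges$parcel_a, atlas$parcel_names),
              match(atlas$edges$parcel_b, atlas$parcel_names))
  blank <- matrix(0, P, P)
  fill <- function(w) {
    m <- blank
    m[ei] <- w
    m[ei[, 2:1]] <- w
    m
  }
  with_seed(seed, {
    n_unrel <- round(unreliable_edge_fraction * nE)
    unreliable <- if (n_unrel > 0) sort(sample.int(nE, n_unrel)) else integer(0)
    controls <- lapply(seq_len(n_controls), function(c) {
      w <- base_weight * (1 + stats::runif(nE, -weight_noise, weight_noise))
      if (length(unreliable))
        w[unreliable] <- w[unreliable] *
          (stats::runif(length(unreliable)) >= unreliable_rate)
      connectome(fill(w), atlas$parcel_names, sprintf("ctl%03d", c))
    })
    patient_cut <- vector("list", length(lesions))
    patients <- lapply(seq_along(lesions), function(i) {
      les <- which(lesions[[i]]$grid == 1L)
      cut <- which(vapply(atlas$trajectories, function(tr)
        any(tr %in% les), TRUE))
      w <- base_weight * (1 + stats::runif(nE, -weight_noise, weight_noise))
      w[cut] <- 0
      patient_cut[[i]] <<- cut
      connectome(fill(w), atlas$parcel_names, lesions[[i]]$subject_id)
    })
    list(controls = controls, patients = patients,
         unreliable_edges = unreliable, patient_cut = patient_cut)
  })
}

# nominal demographic parameters (means/SDs/ranges of a chronic LHS cohort
# and matched controls) used by the covariate generator and the behavioral
# logit standardization
.demographics <- list(
  patient = list(age = c(61.6, 11.6, 39, 92), edu = c(16.5, 2.8, 9, 21)),
  control = list(age = c(61.6, 11.5, 31, 83), edu = c(17.2, 2.5, 12, 21)))

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Default behavioral generating parameters
#'
#' Baseline logits reproduce typical control accuracies (real words 94.3%,
#' 0M 89.7%, 1M 94.3%, MM 93.2%); covariate coefficients (per SD of age /
#' education) are on the scale of the observed demographic effects; duration
#' lognormal parameters match control mean item durations (~1 s real words,
#' ~1.6-1.9 s pseudowords). Trial counts: 200 real words, 20 per pseudoword
#' class.
#'
#' @return Named list of generating parameters.
#' @export
behavior_params <- function() {
  list(baseline_logit = c(real_word = stats::qlogis(0.943),
                          PW0M = stats::qlogis(0.897),
                          PW1M = stats::qlogis(0.943),
                          PWMM = stats::qlogis(0.932)),
       beta_age = -0.13, beta_edu = 0.45,
       trial_counts = c(real_word = 200L, PW0M = 20L, PW1M = 20L,
                        PWMM = 20L),
       duration_meanlog = c(real_word = -0.18, PW0M = 0.47, PW1M = 0.32,
                            PWMM = 0.39),
       duration_sdlog = 0.56)
}

#' Simulate reading behavior for a synthetic cohort
#'
#' Per subject and stimulus class `c` the accuracy follows
#' `logit(p_c) = baseline_c + beta_age * age_z + beta_edu * edu_z
#'  - w_region_c * damage_frac - w_edge_c * n_critical_edges_cut`,
#' where `damage_frac` is the lesioned fraction of the critical region and
#' the edge term counts disconnected critical edges;
#' `n_correct ~ Binomial(n_c, p_c)`. Item durations are lognormal, capped at
#' the 10 s timeout.
#'
#' @param subjects data frame with `subject_id`, `group`, `age`,
#'   `education`.
#' @param truth a `synthetic_truth` list (see [simulate_cohort]); its
#'   `effect_weights`/`edge_weights` give `w_region_c`/`w_edge_c` per class.
#' @param damage_frac numeric vector (one per subject; 0 for controls).
#' @param edges_cut integer vector (critical edges disconnected per
#'   subject; 0 for controls).
#' @param params generating parameters, see [behavior_params].
#' @param seed integer seed.
#' @return Cohort data frame (see [read_cohort_table]).
#' @export
simulate_behavior <- function(subjects, truth, damage_frac, edges_cut,
                              params = behavior_params(), seed = 1L) {
  stopifnot(nrow(subjects) == length(damage_frac),
            nrow(subjects) == length(edges_cut))
  age_z <- (subjects$age - .demographics$patient$age[1]) /
    .demographics$patient$age[2]
  edu_z <- (subjects$education - .demographics$patient$edu[1]) /
    .demographics$patient$edu[2]
  out <- subjects
  with_seed(seed, {
    for (cl2 in STIMULUS_CLASSES) {
      nI <- params$trial_counts[[cl2]]
      lgt <- params$baseline_logit[[cl2]] +
        params$beta_age * age_z + params$beta_edu * edu_z -
        truth$effect_weights[[cl2]] * damage_frac -
        truth$edge_weights[[cl2]] * edges_cut
      p <- stats::plogis(lgt)
      out[[paste0(cl2, "_n")]] <- rep(nI, nrow(out))
      out[[paste0(cl2, "_correct")]] <- stats::rbinom(nrow(out), nI, p)
      dur <- matrix(stats::rlnorm(nrow(out) * nI,
                                  params$duration_meanlog[[cl2]],
                                  params$duration_sdlog),
                    nrow(out), nI)
      dur <- pmin(dur, 10)
      out[[paste0(cl2, "_duration")]] <- rowMeans(dur)
    }
    out
  })
}

#' Generate a complete synthetic stroke cohort
#'
#' Orchestrates atlas, lesions, covariates, connectomes, and behavior into
#' one seeded, bitwise-reproducible cohort with exported ground truth.
#' With `region_effect = 0` and `edge_effect = 0` (the default) behavior
#' depends only on covariates and binomial noise — a null cohort for error
#' rate studies. A nonzero `region_effect` wires a graded deficit (on the
#' pseudoword classes) to the lesioned fraction of a contiguous critical
#' region grown at the territory center; a nonzero `edge_effect` wires a
#' binary deficit to disconnection of one critical edge (the reliable edge
#' whose cut fraction is closest to 1/2, i.e. maximal variance).
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_patients,n_controls cohort sizes (defaults 64 / 71).
#' @param shape,K,voxel_mm atlas geometry (defaults 20x24x20, 4 left
#'   parcels, 2 mm).
#' @param region_effect logit shift at full damage of the critical region
#'   (e.g. 4 = severe; applied with a negative sign).
#' @param region_size critical region size in voxels (default 100).
#' @param edge_effect logit shift per disconnected critical edge.
#' @param volume_lognormal,territory_bias lesion generator controls, see
#'   [simulate_lesions].
#' @param params behavioral parameters, see [behavior_params].
#' @return List of class `synthetic_cohort`: `atlas`, `masks`,
#'   `connectomes` (`$controls`, `$patients`), `cohort` (data frame,
#'   patients then controls, with `lesion_volume_cm3`), `truth`
#'   (`synthetic_truth`: `critical_voxels`, `critical_edge`,
#'   `effect_weights`, `edge_weights`, `covariate_coefficients`,
#'   `baseline_logit`, `trial_counts`, `seed`).
#' @export
simulate_cohort <- function(seed = 1L, n_patients = 64L, n_controls = 71L,
                            shape = c(20L, 24L, 20L), K = 4L, voxel_mm = 2,
                            region_effect = 0, region_size = 100L,
                            edge_effect = 0,
                            volume_lognormal = c(5.93, 0.75),
                            territory_bias = 0.7,
                            params = behavior_params()) {
  seed <- as.integer(seed)
  atlas <- make_atlas(shape, K, seed = seed)
  masks <- simulate_lesions(n_patients, atlas, volume_lognormal,
                            territory_bias, voxel_mm, seed = seed + 1L)
  conn <- simulate_connectomes(atlas, masks, n_controls, seed = seed + 2L)

  dem <- with_seed(seed + 3L, {
    dp <- .demographics$patient; dc <- .demographics$control
    data.frame(
      subject_id = c(vapply(masks, `[[`, "", "subject_id"),
                     sprintf("ctl%03d", seq_len(n_controls))),
      group = rep(c("patient", "control"), c(n_patients, n_controls)),
      age = c(.rtruncnorm(n_patients, dp$age[1], dp$age[2], dp$age[3],
                          dp$age[4]),
              .rtruncnorm(n_controls, dc$age[1], dc$age[2], dc$age[3],
                          dc$age[4])),
      education = round(c(
        .rtruncnorm(n_patients, dp$edu[1], dp$edu[2], dp$edu[3], dp$edu[4]),
        .rtruncnorm(n_controls, dc$edu[1], dc$edu[2], dc$edu[3],
                    dc$edu[4]))))
  })

  # ground truth: critical region (graded, voxel level) and critical edge
  critical_voxels <- integer(0)
  if (region_effect != 0) {
    ctr <- .territory_voxels(atlas, radius = 1)[1]
    critical_voxels <- with_seed(seed + 4L,
                                 .grow_region(ctr, region_size, atlas))
  }
  critical_edge <- integer(0)
  if (edge_effect != 0) {
    reliable <- setdiff(seq_len(nrow(atlas$edges)), conn$unreliable_edges)
    cutfrac <- vapply(reliable, function(e)
      mean(vapply(conn$patient_cut, function(ct) e %in% ct, TRUE)), 0)
    critical_edge <- reliable[which.min(abs(cutfrac - 0.5))]
  }
  zero_w <- c(real_word = 0, PW0M = 0, PW1M = 0, PWMM = 0)
  effect_weights <- zero_w
  if (region_effect != 0)
    effect_weights[c("PW0M", "PW1M", "PWMM")] <- region_effect
  edge_weights <- zero_w
  if (edge_effect != 0)
    edge_weights[c("PW0M", "PW1M", "PWMM")] <- edge_effect
  truth <- list(critical_voxels = critical_voxels,
                critical_edge = critical_edge,
                effect_weights = effect_weights,
                edge_weights = edge_weights,
                covariate_coefficients = c(age = params$beta_age,
                                           education = params$beta_edu),
                baseline_logit = params$baseline_logit,
                trial_counts = params$trial_counts,
                unreliable_edges = conn$unreliable_edges,
                patient_cut = conn$patient_cut,
                seed = seed)
  class(truth) <- "synthetic_truth"

  damage <- c(vapply(masks, function(m) {
    if (!length(critical_voxels)) 0
    else sum(m$grid[critical_voxels]) / length(critical_voxels)
  }, 0), rep(0, n_controls))
  cut <- c(vapply(conn$patient_cut, function(ct)
    sum(critical_edge %in% ct), 0L), rep(0L, n_controls))

  cohort <- simulate_behavior(dem, truth, damage, cut, params,
                              seed = seed + 5L)
  cohort$lesion_volume_cm3 <- c(vapply(masks, lesion_volume_cm3, 0),
                                rep(NA_real_, n_controls))

  structure(list(atlas = atlas, masks = masks,
                 connectomes = conn[c("controls", "patients")],
                 cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients / %d controls on a %s grid (seed %d)\n",
              sum(x$cohort$group == "patient"),
              sum(x$cohort$group == "control"),
              paste(x$atlas$shape, collapse = "x"), x$truth$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Masks as NIfTI, connectomes and labels as TSV, the cohort table as TSV,
#' and the ground truth as JSON.
#'
#' @param x a [simulate_cohort] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(x, dir) {
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "connectomes"), showWarnings = FALSE)
  for (m in x$masks)
    write_lesion_mask(m, file.path(dir, "masks",
                                   paste0(m$subject_id, ".nii.gz")))
  writeLines(x$atlas$parcel_names, file.path(dir, "connectomes", "labels.tsv"))
  for (cn in c(x$connectomes$controls, x$connectomes$patients))
    write_connectome(cn, file.path(dir, "connectomes",
                                   paste0(cn$subject_id, ".tsv")))
  write_cohort_table(x$cohort, file.path(dir, "cohort.tsv"))
  tr <- unclass(x$truth)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Recovery metrics against simulation ground truth
#'
#' Dice overlap `2|A^B| / (|A|+|B|)` and, for voxel sets, the distance
#' between the centroids of the detected and true sets (in voxels). Both
#' sets empty gives dice 0 (with a message).
#'
#' @param detected integer vector of voxel linear indices, or character
#'   vector of edge keys (`"A|B"`).
#' @param truth same representation as `detected`.
#' @param dim grid dimensions (required for voxel centroid distance).
#' @return List: `dice`, `centroid_distance` (voxels; `NA` for edge sets or
#'   empty sets), `hit` (`dice > 0`).
#' @export
recovery_metrics <- function(detected, truth, dim = NULL) {
  a <- unique(detected); b <- unique(truth)
  if (!length(a) && !length(b)) {
    message("recovery_metrics: both sets empty; dice defined as 0")
    return(list(dice = 0, centroid_distance = NA_real_, hit = FALSE))
  }
  inter <- length(intersect(a, b))
  dice <- 2 * inter / (length(a) + length(b))
  cdist <- NA_real_
  if (!is.null(dim) && is.numeric(a) && is.numeric(b) && length(a) &&
      length(b)) {
    ca <- colMeans(arrayInd(a, dim))
    cb <- colMeans(arrayInd(b, dim))
    cdist <- sqrt(sum((ca - cb)^2))
  }
  list(dice = dice, centroid_distance = cdist, hit = dice > 0)
}

#' Edge key helper: canonical "A|B" identifiers for unordered parcel pairs
#' @param parcel_a,parcel_b character vectors.
#' @return Character vector of canonical keys.
#' @export
edge_key <- function(parcel_a, parcel_b) {
  ifelse(parcel_a < parcel_b, paste(parcel_a, parcel_b, sep = "|"),
         paste(parcel_b, parcel_a, sep = "|"))
}
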