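# Voxelwise SVR lesion-symptom mapping: coverage-filtered design
# construction, clusterwise permutation FWER, cluster geometry reporting.

#' Build the voxelwise design matrix from a cohort of lesion masks
#'
#' Columns are voxels lesioned in at least `min_coverage` of the patients
#' ("at least 10%" by default, the conventional power filter); entries are
#' 0/1 lesion status before residualization.
#'
#' @param masks list of [lesion_mask] with identical geometry.
#' @param min_coverage minimum lesioned fraction (inclusive, default 0.10).
#' @return Object of class `voxel_design`: `X` (patients x voxels, rows named
#'   by subject id), `voxel_index` (k x 3 integer matrix of 1-based grid
#'   coordinates), `coverage` (per retained voxel), `dim`, `affine`,
#'   `min_coverage`.
#' @export
build_voxel_design <- function(masks, min_coverage = 0.10) {
  if (length(masks) < 10L)
    stopf("voxelwise LSM needs >= 10 masks, got %d", length(masks))
  d <- dim(masks[[1]]$grid)
  aff <- masks[[1]]$affine
  for (m in masks) {
    if (!all(dim(m$grid) == d) || !same_affine(m$affine, aff))
      stopf("cohort inconsistency: mask '%s' geometry differs", m$subject_id)
  }
  n <- length(masks)
  flat <- vapply(masks, function(m) as.vector(m$grid), numeric(prod(d)))
  counts <- rowSums(flat)
  keep <- which(counts / n >= min_coverage)
  if (length(keep) == 0L)
    stopf("empty design: no voxel reaches coverage %.2f", min_coverage)
  X <- t(flat[keep, , drop = FALSE])
  rownames(X) <- vapply(masks, `[[`, "", "subject_id")
  structure(list(X = X, voxel_index = arrayInd(keep, d),
                 linear_index = keep, coverage = counts[keep] / n,
                 dim = d, affine = aff, min_coverage = min_coverage),
            class = "voxel_design")
}

#' @export
print.voxel_design <- function(x, ...) {
  cat(sprintf("<voxel_design> %d patients x %d voxels (coverage >= %.2f on %s grid)\n",
              nrow(x$X), ncol(x$X), x$min_coverage,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# neighbor offsets for a given 3D connectivity
.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  lim <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L,
                stopf("connectivity must be 6, 18 or 26"))
  g[ord > 0 & ord <= lim, , drop = FALSE]
}

#' Label connected components of a 3D binary array
#'
#' Breadth-first labeling under 6-, 18-, or 26-neighborhood adjacency.
#'
#' @param mask 3D logical/0-1 array.
#' @param connectivity 6, 18, or 26.
#' @return Integer array of the same shape: 0 for background, components
#'   labeled 1, 2, ... in discovery order.
#' @export
label_clusters <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stopf("mask must be 3D")
  off <- .neighbor_offsets(connectivity)
  lab <- array(0L, d)
  fg <- which(mask > 0)
  if (!length(fg)) return(lab)
  cur <- 0L
  for (v in fg) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      ijk <- arrayInd(queue, d)
      queue <- integer(0)
      for (r in seq_len(nrow(off))) {
        nb <- ijk
        nb[, 1] <- nb[, 1] + off[r, 1]
        nb[, 2] <- nb[, 2] + off[r, 2]
        nb[, 3] <- nb[, 3] + off[r, 3]
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
          (nb[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[mask[lin] > 0 & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# largest component size among suprathreshold design columns of one map
.max_cluster_size <- function(supra_cols, design, connectivity) {
  n_sup <- sum(supra_cols)
  if (n_sup <= 1L) return(n_sup)
  m <- array(0L, design$dim)
  m[design$linear_index[supra_cols]] <- 1L
  lab <- label_clusters(m, connectivity)
  max(tabulate(lab[lab > 0L]))
}

#' Voxel-based SVR lesion-symptom mapping
#'
#' Fits the full SVR-VLSM pipeline for one behavioral contrast: lesion
#' coverage filtering, residualization of nuisance and behavioral covariates
#' out of both the lesion matrix and the dependent variable, linear-kernel
#' SVR with beta back-projection, voxelwise one-tailed (negative) permutation
#' p-values, and clusterwise familywise error correction: suprathreshold
#' voxels (`p < voxel_forming_p`) are grouped into connected components and
#' each observed cluster size is referred to the permutation distribution of
#' the maximal suprathreshold cluster size.
#'
#' @param masks list of [lesion_mask] (the patients).
#' @param cohort cohort data frame (see [read_cohort_table]).
#' @param contrast a [contrast_spec] or the name of a built-in contrast
#'   (see [reading_contrasts]).
#' @param cfg an [svr_config].
#' @param scheme a [perm_scheme].
#' @param min_coverage minimum lesioned fraction per voxel (default 0.10).
#' @return Object of class `c("svr_vlsm", "svr_lsm")` with components
#'   `clusters` (data frame: id, n_voxels, size_cm3, center of mass in mm,
#'   p_cluster, significant), `beta_map`, `p_map`, `cluster_map`
#'   ([stat_map]s; unsampled voxels carry 0 in the beta map and the p map),
#'   `voxel` (per-voxel beta and p), `null_max_size`, `design`, `target`,
#'   `cfg`, `scheme`.
#' @export
svr_vlsm <- function(masks, cohort, contrast = "pseudoword_lexicality",
                     cfg = svr_config(), scheme = perm_scheme(),
                     min_coverage = 0.10) {
  cl <- match.call()
  if (is.character(contrast)) contrast <- reading_contrasts(contrast)
  design <- build_voxel_design(masks, min_coverage)
  target <- build_contrast_target(cohort, contrast, masks)
  if (!all(target$subject_id %in% rownames(design$X)))
    stopf("masks missing for subjects: %s",
          paste(setdiff(target$subject_id, rownames(design$X)), collapse = ", "))
  X <- design$X[target$subject_id, , drop = FALSE]

  Cov <- covariate_matrix(target)
  Xr <- residualize(X, Cov)
  yr <- residualize(target$y, Cov)

  pn <- permutation_null(Xr, yr, cfg, scheme)

  # observed suprathreshold map and clusters
  supra <- pn$p < scheme$voxel_forming_p
  obs_mask <- array(0L, design$dim)
  obs_mask[design$linear_index[supra]] <- 1L
  lab <- label_clusters(obs_mask, scheme$connectivity)
  n_clust <- max(lab)

  # each permutation's own suprathreshold map: within-column rank of the
  # permuted beta among all permuted betas (ties max) / n_perm
  rank_p <- apply(pn$perm_beta, 2, rank, ties.method = "max") / scheme$n_perm
  null_max <- vapply(seq_len(scheme$n_perm), function(b) {
    .max_cluster_size(rank_p[b, ] < scheme$voxel_forming_p, design,
                      scheme$connectivity)
  }, integer(1))

  vox_mm3 <- .voxel_volume_mm3(design$affine)
  clusters <- if (n_clust > 0L) {
    rows <- lapply(seq_len(n_clust), function(ci) {
      vox <- which(lab == ci)
      ijk <- arrayInd(vox, design$dim)
      com <- colMeans(ijk) - 1 # 0-based voxel coordinates
      com_mm <- drop(design$affine %*% c(com, 1))[1:3]
      size <- length(vox)
      p_c <- (1 + sum(null_max >= size)) / (scheme$n_perm + 1)
      data.frame(cluster = ci, n_voxels = size,
                 size_cm3 = size * vox_mm3 / 1000,
                 com_x = com_mm[1], com_y = com_mm[2], com_z = com_mm[3],
                 p_cluster = p_c, significant = p_c < scheme$alpha)
    })
    out <- do.call(rbind, rows)
    out[order(out$p_cluster, -out$size_cm3), , drop = FALSE]
  } else {
    message("svr_vlsm: no suprathreshold voxels; empty cluster result")
    data.frame(cluster = integer(), n_voxels = integer(),
               size_cm3 = numeric(), com_x = numeric(), com_y = numeric(),
               com_z = numeric(), p_cluster = numeric(),
               significant = logical())
  }

  beta_arr <- array(0, design$dim)
  beta_arr[design$linear_index] <- pn$beta
  p_arr <- array(0, design$dim) # 0 = sentinel for unsampled voxels
  p_arr[design$linear_index] <- pn$p
  sig_ids <- clusters$cluster[clusters$significant]
  clu_arr <- array(0L, design$dim)
  clu_arr[lab %in% sig_ids] <- lab[lab %in% sig_ids]

  structure(list(call = cl, contrast = contrast, clusters = clusters,
                 beta_map = stat_map(beta_arr, design$affine, "beta"),
                 p_map = stat_map(p_arr, design$affine, "p"),
                 cluster_map = stat_map(clu_arr + 0, design$affine,
                                        "thresholded"),
                 voxel = data.frame(beta = pn$beta, p = pn$p),
                 cluster_label = lab,
                 null_max_size = null_max, design = design, target = target,
                 cfg = cfg, scheme = scheme),
            class = c("svr_vlsm", "svr_lsm"))
}

#' Format a cluster table for reporting
#'
#' Sizes in cm^3 to 3 decimals and MNI-style center-of-mass coordinates to
#' 1 decimal (unweighted mean of voxel centers through the affine), rows
#' sorted by cluster p then size descending.
#'
#' @param fit an `svr_vlsm` object (or its `clusters` data frame).
#' @return Data frame with formatted columns.
#' @export
report_clusters <- function(fit) {
  cl <- if (inherits(fit, "svr_vlsm")) fit$clusters else fit
  if (nrow(cl) == 0L) return(cl)
  cl <- cl[order(cl$p_cluster, -cl$size_cm3), , drop = FALSE]
  data.frame(cluster = cl$cluster,
             size_cm3 = sprintf("%.3f", cl$size_cm3),
             center_of_mass = sprintf("%.1f, %.1f, %.1f",
                                      round(cl$com_x, 1), round(cl$com_y, 1),
                                      round(cl$com_z, 1)),
             p_cluster = cl$p_cluster, significant = cl$significant,
             row.names = NULL)
}

#' Write VLSM results to disk
#'
#' Beta map, voxelwise p map and significant-cluster label map as NIfTI, the
#' cluster table as TSV, and a JSON run summary (seeds, thresholds, subject
#' count).
#'
#' @param fit an `svr_vlsm` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_vlsm_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stat_map(fit$beta_map, file.path(dir, "beta.nii"))
  write_stat_map(fit$p_map, file.path(dir, "p.nii"))
  write_stat_map(fit$cluster_map, file.path(dir, "clusters.nii"))
  utils::write.table(fit$clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(contrast = fit$contrast$name,
                  n_subjects = length(fit$target$y),
                  n_voxels = ncol(fit$design$X),
                  min_coverage = fit$design$min_coverage,
                  kernel = fit$cfg$kernel, C = fit$cfg$C,
                  epsilon = fit$cfg$epsilon,
                  n_perm = fit$scheme$n_perm, alpha = fit$scheme$alpha,
                  voxel_forming_p = fit$scheme$voxel_forming_p,
                  connectivity = fit$scheme$connectivity,
                  seed = fit$scheme$seed,
                  n_significant_clusters = sum(fit$clusters$significant))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
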