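# Connectome-based SVR lesion-symptom mapping: binary disconnectome
# construction, edge filtering, and edge-/parcel-level permutation FWER.

#' Binarize a patient connectome against a control cohort
#'
#' An edge is disconnected (1) iff it is absent in the patient's connectome
#' but present in 100% of control connectomes; edges not present in every
#' control are excluded from analysis altogether (analyzable mask 0), which
#' reduces Type I error from unreliably reconstructed connections. "Absent"
#' means weight exactly 0 up to `tol` (cross-sectional-area weights are zero
#' when no streamline survives).
#'
#' @param patient a [connectome].
#' @param controls list of at least 2 control [connectome]s with identical
#'   parcel labels.
#' @param tol weights below this are treated as 0 (default 1e-12).
#' @return Object of class `disconnection_matrix`: `labels`, `D` (binary
#'   symmetric, 1 = disconnected), `analyzable` (binary symmetric, 1 = edge
#'   present in all controls).
#' @export
binarize_disconnection <- function(patient, controls, tol = 1e-12) {
  stopifnot(inherits(patient, "connectome"), length(controls) >= 2L)
  for (ctl in controls)
    if (!identical(ctl$labels, patient$labels))
      stopf("parcel labels of a control do not match the patient connectome")
  K <- length(patient$labels)
  analyzable <- matrix(1L, K, K)
  for (ctl in controls)
    analyzable <- analyzable * (ctl$weights > tol)
  D <- analyzable * (patient$weights <= tol)
  diag(D) <- 0L; diag(analyzable) <- 0L
  storage.mode(D) <- "integer"; storage.mode(analyzable) <- "integer"
  dimnames(D) <- dimnames(analyzable) <- list(patient$labels, patient$labels)
  structure(list(labels = patient$labels, D = D, analyzable = analyzable,
                 subject_id = patient$subject_id),
            class = "disconnection_matrix")
}

#' @export
print.disconnection_matrix <- function(x, ...) {
  cat(sprintf("<disconnection_matrix> %d parcels, %d disconnected / %d analyzable edges\n",
              length(x$labels), sum(x$D[upper.tri(x$D)]),
              sum(x$analyzable[upper.tri(x$analyzable)])))
  invisible(x)
}

#' Build the edge-level design matrix from patient disconnectomes
#'
#' Retains upper-triangle edges that are analyzable (present in all
#' controls — shared across patients by construction) and disconnected in
#' strictly more than `min_fraction` of patients (the "greater than 10%"
#' rule; note the voxel filter is inclusive while this one is strict,
#' following the differing wording of the two conventions).
#'
#' @param disconn list of [binarize_disconnection] outputs, >= 10 patients.
#' @param min_fraction strict lower bound on disconnection fraction
#'   (default 0.10).
#' @return Object of class `edge_design`: `X` (patients x edges 0/1, rows
#'   named by subject id), `edges` (data frame `parcel_a`, `parcel_b`),
#'   `fraction` (per retained edge), `labels`, `min_fraction`.
#' @export
build_edge_design <- function(disconn, min_fraction = 0.10) {
  if (length(disconn) < 10L)
    stopf("edge-level LSM needs >= 10 patients, got %d", length(disconn))
  labels <- disconn[[1]]$labels
  analyzable <- disconn[[1]]$analyzable
  for (d in disconn) {
    if (!identical(d$labels, labels)) stopf("parcel label mismatch across patients")
    if (!identical(d$analyzable, analyzable))
      stopf("analyzable mask differs across patients; binarize against one control cohort")
  }
  ut <- which(upper.tri(analyzable) & analyzable == 1L)
  if (!length(ut)) stopf("empty design: no analyzable edges")
  X <- t(vapply(disconn, function(d) as.integer(d$D[ut]), integer(length(ut))))
  frac <- colMeans(X)
  keep <- frac > min_fraction
  if (!any(keep))
    stopf("empty design: no edge disconnected in > %.0f%% of patients",
          100 * min_fraction)
  X <- X[, keep, drop = FALSE]
  ij <- arrayInd(ut[keep], dim(analyzable))
  rn <- vapply(disconn, function(d)
    if (is.null(d$subject_id)) NA_character_ else d$subject_id, "")
  if (!anyNA(rn)) rownames(X) <- rn
  structure(list(X = X,
                 edges = data.frame(parcel_a = labels[ij[, 1]],
                                    parcel_b = labels[ij[, 2]]),
                 fraction = frac[keep], labels = labels,
                 analyzable = analyzable, min_fraction = min_fraction),
            class = "edge_design")
}

#' @export
print.edge_design <- function(x, ...) {
  cat(sprintf("<edge_design> %d patients x %d edges (disconnection fraction > %.2f)\n",
              nrow(x$X), ncol(x$X), x$min_fraction))
  invisible(x)
}

# parcel statistic: sum of negative parts of beta over retained incident
# edges; beta may be a matrix (rows = permutations)
.parcel_stat <- function(beta, incidence) {
  neg <- pmax(-beta, 0)
  if (is.matrix(neg)) neg %*% incidence else drop(neg %*% incidence)
}

#' Connectome-based SVR lesion-symptom mapping
#'
#' Fits the full SVR-CLSM pipeline for one behavioral contrast: binary
#' disconnectome construction, edge filtering, residualization of covariates
#' out of the edge matrix and the dependent variable, SVR beta
#' back-projection, and permutation familywise error control. Edge-level
#' correction is single-step maxT (the null statistic of permutation `b` is
#' the minimum beta across edges, matching the one-tailed negative
#' convention); connectome space has no spatial clusters, so no cluster
#' forming is involved. Parcel-level results aggregate each parcel's
#' retained incident edges by the sum of negative beta parts and use the
#' per-permutation maximum of that statistic across parcels, reusing the
#' same permutation stream.
#'
#' @param patients list of patient [connectome]s (with `subject_id` fields)
#'   or pre-built [binarize_disconnection] outputs.
#' @param controls list of control [connectome]s (ignored when `patients`
#'   are already disconnection matrices).
#' @param cohort cohort data frame; must carry `lesion_volume_cm3` for
#'   patients (or supply `masks`).
#' @param contrast a [contrast_spec] or built-in contrast name.
#' @param cfg an [svr_config].
#' @param scheme a [perm_scheme].
#' @param min_fraction strict disconnection-fraction filter (default 0.10).
#' @param masks optional list of [lesion_mask] for lesion volumes.
#' @return Object of class `c("svr_clsm", "svr_lsm")` with `edges` (data
#'   frame: parcel_a, parcel_b, beta, p_fwer, significant), `parcels` (data
#'   frame: parcel, statistic, p_fwer, significant, analyzable), `design`,
#'   `target`, `null_min_beta`, `null_max_parcel`, `cfg`, `scheme`.
#' @export
svr_clsm <- function(patients, controls = NULL, cohort,
                     contrast = "pseudoword_lexicality",
                     cfg = svr_config(), scheme = perm_scheme(),
                     min_fraction = 0.10, masks = NULL) {
  cl <- match.call()
  if (is.character(contrast)) contrast <- reading_contrasts(contrast)
  if (all(vapply(patients, inherits, TRUE, "connectome"))) {
    if (is.null(controls)) stopf("control connectomes required")
    disconn <- lapply(patients, binarize_disconnection, controls = controls)
  } else disconn <- patients
  design <- build_edge_design(disconn, min_fraction)
  target <- build_contrast_target(cohort, contrast, masks)
  if (is.null(rownames(design$X)))
    stopf("patient connectomes lack subject ids; cannot align with cohort")
  if (!all(target$subject_id %in% rownames(design$X)))
    stopf("connectomes missing for subjects: %s",
          paste(setdiff(target$subject_id, rownames(design$X)), collapse = ", "))
  X <- design$X[target$subject_id, , drop = FALSE]

  Cov <- covariate_matrix(target)
  Xr <- residualize(X, Cov)
  yr <- residualize(target$y, Cov)

  pn <- permutation_null(Xr, yr, cfg, scheme)

  # single-step maxT at the edge level (min beta under the negative tail)
  null_min <- apply(pn$perm_beta, 1, min)
  p_fwer <- vapply(pn$beta, function(b)
    (1 + sum(null_min <= b)) / (scheme$n_perm + 1), 0)
  edges <- cbind(design$edges,
                 data.frame(beta = pn$beta, p_fwer = p_fwer,
                            significant = p_fwer < scheme$alpha,
                            fraction = design$fraction))

  # parcel level: reuse the identical permutation stream
  K <- length(design$labels)
  incidence <- matrix(0, ncol(X), K,
                      dimnames = list(NULL, design$labels))
  for (e in seq_len(ncol(X))) {
    incidence[e, design$edges$parcel_a[e]] <- 1
    incidence[e, design$edges$parcel_b[e]] <- 1
  }
  analyzable_parcel <- colSums(incidence) > 0
  s_obs <- .parcel_stat(pn$beta, incidence)
  S_perm <- .parcel_stat(pn$perm_beta, incidence) # n_perm x K
  null_max_parcel <- apply(S_perm[, analyzable_parcel, drop = FALSE], 1, max)
  p_parcel <- ifelse(analyzable_parcel,
                     (1 + vapply(s_obs, function(s)
                       sum(null_max_parcel >= s), 0L)) / (scheme$n_perm + 1),
                     NA_real_)
  parcels <- data.frame(parcel = design$labels,
                        statistic = ifelse(analyzable_parcel, s_obs, NA_real_),
                        p_fwer = p_parcel,
                        significant = !is.na(p_parcel) & p_parcel < scheme$alpha,
                        analyzable = analyzable_parcel,
                        n_edges = colSums(incidence),
                        row.names = NULL)

  structure(list(call = cl, contrast = contrast, edges = edges,
                 parcels = parcels, beta = pn$beta,
                 null_min_beta = null_min, null_max_parcel = null_max_parcel,
                 design = design, target = target, cfg = cfg,
                 scheme = scheme),
            class = c("svr_clsm", "svr_lsm"))
}

#' Write CLSM results to disk
#'
#' Edge result TSV, parcel result TSV, per-patient binary disconnectome
#' TSVs, and a JSON run summary.
#'
#' @param fit an `svr_clsm` object.
#' @param dir output directory.
#' @param disconn optional list of disconnection matrices to dump as TSVs.
#' @return `dir`, invisibly.
#' @export
write_clsm_results <- function(fit, dir, disconn = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_table(fit$edges, file.path(dir, "edges.tsv"))
  utils::write.table(fit$parcels, file.path(dir, "parcels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(disconn)) {
    for (d in disconn)
      utils::write.table(d$D, file.path(dir, sprintf("disconnectome_%s.tsv",
                                                     d$subject_id)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  summary <- list(contrast = fit$contrast$name,
                  n_subjects = length(fit$target$y),
                  n_edges = ncol(fit$design$X),
                  min_fraction = fit$design$min_fraction,
                  kernel = fit$cfg$kernel,
                  n_perm = fit$scheme$n_perm, alpha = fit$scheme$alpha,
                  seed = fit$scheme$seed,
                  n_significant_edges = sum(fit$edges$significant),
                  n_significant_parcels = sum(fit$parcels$significant))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
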