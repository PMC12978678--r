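# Cohort I/O: lesion masks, connectomes, cohort tables, statistical maps.

#' Construct a lesion mask object
#'
#' A lesion mask is a 3D binary grid in a common (template) space together
#' with the voxel-to-mm affine. All masks of a cohort must share grid shape
#' and affine.
#'
#' @param grid 3D array; coerced to 0/1 by thresholding at 0.5 (values
#'   strictly greater than 0.5 become 1). Interpolated masks may carry
#'   fractional values; traced masks are already binary.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param subject_id character scalar.
#' @return An object of class `lesion_mask` with fields `subject_id`, `grid`
#'   (integer 0/1 array), `affine`, and `voxel_volume_mm3`.
#' @examples
#' m <- lesion_mask(array(c(0, 0.2, 0.9, 1), c(1, 2, 2)), diag(4), "s01")
#' sum(m$grid) # 2
#' @export
lesion_mask <- function(grid, affine = diag(4), subject_id = "subject") {
  if (length(dim(grid)) != 3L)
    stopf("lesion mask for '%s' must be a 3D volume, got %d dimensions",
          subject_id, length(dim(grid)))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stopf("affine must be a 4x4 matrix")
  vv <- .voxel_volume_mm3(affine)
  if (!is.finite(vv) || vv <= 0) stopf("affine implies non-positive voxel volume")
  g <- array(as.integer(grid > 0.5), dim = dim(grid))
  structure(list(subject_id = as.character(subject_id), grid = g,
                 affine = affine, voxel_volume_mm3 = vv),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s: %s grid, %d lesioned voxels (%.3f cm^3)\n",
              x$subject_id, paste(dim(x$grid), collapse = "x"),
              sum(x$grid), lesion_volume_cm3(x)))
  invisible(x)
}

#' Read a cohort of lesion masks from NIfTI files
#'
#' Voxels with intensity > 0.5 are set to 1, all others to 0. All files must
#' share grid shape and affine (within 1e-4); the first file fixes the cohort
#' geometry.
#'
#' @param paths character vector of NIfTI file paths.
#' @param subject_ids optional character vector; defaults to file basenames.
#' @return List of [lesion_mask] objects, in input order.
#' @export
read_lesion_masks <- function(paths, subject_ids = NULL) {
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  ref <- NULL
  masks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    d <- dim(img)
    if (length(d) != 3L)
      stopf("'%s' is %dD; lesion masks must be 3D volumes", paths[i], length(d))
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    aff <- matrix(as.numeric(aff), 4, 4)
    if (is.null(ref)) {
      ref <- list(dim = d, affine = aff)
    } else {
      if (!all(d == ref$dim))
        stopf("cohort inconsistency: '%s' has grid %s, expected %s",
              paths[i], paste(d, collapse = "x"), paste(ref$dim, collapse = "x"))
      if (!same_affine(aff, ref$affine))
        stopf("cohort inconsistency: '%s' has a different affine than the first mask",
              paths[i])
    }
    masks[[i]] <- lesion_mask(as.array(img), aff, subject_ids[i])
  }
  masks
}

#' Write a lesion mask to a NIfTI file
#' @param mask a [lesion_mask].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_lesion_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$grid), dim = dim(mask$grid)))
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Lesion volume in cubic centimetres
#'
#' `(number of lesioned voxels) * voxel_volume_mm3 / 1000`, exactly.
#' Additive over disjoint lesion components.
#'
#' @param mask a [lesion_mask].
#' @return Non-negative numeric scalar (cm^3).
#' @examples
#' m <- lesion_mask(array(rep(1, 10), c(10, 1, 1)), diag(4))
#' lesion_volume_cm3(m) # 0.010
#' @export
lesion_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$grid) * mask$voxel_volume_mm3 / 1000
}

#' Construct a structural connectome
#'
#' Weighted adjacency over atlas parcels. Each edge weight is proportional to
#' the cross-sectional area of white matter connecting the two parcels, so a
#' weight of exactly 0 means the connection is absent. Small asymmetries
#' (<= 1e-6) from upstream I/O are symmetrized by averaging; the diagonal is
#' forced to 0.
#'
#' @param weights square numeric matrix, non-negative.
#' @param labels character vector of parcel labels, one per row/column.
#' @param subject_id optional subject identifier carried through the
#'   disconnectome pipeline.
#' @return Object of class `connectome` with fields `labels`, `weights` and
#'   `subject_id`.
#' @export
connectome <- function(weights, labels = NULL, subject_id = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stopf("connectome matrix must be square, got %dx%d", nrow(weights), ncol(weights))
  if (is.null(labels)) labels <- paste0("P", seq_len(nrow(weights)))
  labels <- as.character(labels)
  if (length(labels) != nrow(weights))
    stopf("%d labels for a %d-parcel matrix", length(labels), nrow(weights))
  if (anyDuplicated(labels)) stopf("duplicated parcel labels")
  if (any(weights < 0)) stopf("negative connectome weights are not allowed")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-6)
    stopf("connectome asymmetry %.3g exceeds tolerance 1e-6", asym)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warnf("nonzero connectome diagonal zeroed")
    diag(weights) <- 0
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 subject_id = if (is.null(subject_id)) NULL
                              else as.character(subject_id)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectome> %d parcels, %d/%d nonzero edges\n",
              length(x$labels), sum(w > 0), length(w)))
  invisible(x)
}

#' Read a connectome from a delimited matrix file
#'
#' @param path TSV file holding the square weight matrix (no header).
#' @param labels_path optional TSV file with one parcel label per line; if
#'   omitted, labels default to `P1..Pn`.
#' @return A [connectome].
#' @export
read_connectome <- function(path, labels_path = NULL) {
  w <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(w) <- NULL
  labels <- if (!is.null(labels_path)) readLines(labels_path) else NULL
  connectome(w, labels)
}

#' Write a connectome (and optionally its labels) to TSV
#' @param x a [connectome].
#' @param path matrix output path.
#' @param labels_path optional labels output path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, labels_path = NULL) {
  utils::write.table(x$weights, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(labels_path)) writeLines(x$labels, labels_path)
  invisible(path)
}

#' Construct a statistical map aligned to the cohort grid
#'
#' @param values 3D numeric array.
#' @param affine 4x4 affine shared with the cohort lesion masks.
#' @param kind one of `"beta"`, `"p"`, `"thresholded"`.
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(values, affine, kind = c("beta", "p", "thresholded")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stopf("stat map values must be 3D")
  structure(list(values = values, affine = as.matrix(affine), kind = kind),
            class = "stat_map")
}

#' Write a statistical map to NIfTI
#' @param map a [stat_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a statistical map from NIfTI
#' @param path NIfTI file.
#' @param kind map kind, see [stat_map].
#' @return A [stat_map].
#' @export
read_stat_map <- function(path, kind = "beta") {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  stat_map(as.array(img), aff, kind)
}

#' Write an edge-level result table to TSV
#'
#' Columns: `parcel_a`, `parcel_b`, `beta`, `p_fwer`, `significant`.
#' An empty result list yields a header-only file.
#'
#' @param results data frame of edge results (as in `svr_clsm()$edges`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(results, path) {
  cols <- c("parcel_a", "parcel_b", "beta", "p_fwer", "significant")
  if (is.null(results) || nrow(results) == 0L)
    results <- data.frame(parcel_a = character(), parcel_b = character(),
                          beta = numeric(), p_fwer = numeric(),
                          significant = logical())
  utils::write.table(results[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an edge-level result table written by [write_edge_table]
#' @param path TSV path.
#' @return Data frame with the edge-result columns.
#' @export
read_edge_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "logical"))
}

#' Read / write a cohort table
#'
#' A cohort table has one row per subject with columns `subject_id`, `group`
#' (`control`/`patient`), `age`, `education`, optionally `lesion_volume_cm3`
#' (patients), and per stimulus class `<class>_n`, `<class>_correct`,
#' `<class>_duration` (mean seconds per item) for classes `real_word`,
#' `PW0M`, `PW1M`, `PWMM`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_cohort_table
#' @param cohort cohort data frame.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
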