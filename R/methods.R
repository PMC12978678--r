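# print / summary / coef / plot methods for fitted lesion-symptom maps

#' @export
print.svr_vlsm <- function(x, ...) {
  cat(sprintf("SVR-VLSM: contrast '%s', %d patients, %d voxels (coverage >= %.2f)\n",
              x$contrast$name, length(x$target$y), ncol(x$design$X),
              x$design$min_coverage))
  cat(sprintf("  %d permutations, voxel-forming p < %g, clusterwise FWER alpha = %g, connectivity %d\n",
              x$scheme$n_perm, x$scheme$voxel_forming_p, x$scheme$alpha,
              x$scheme$connectivity))
  nsig <- sum(x$clusters$significant)
  if (nrow(x$clusters) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    cat(sprintf("  %d cluster(s), %d significant\n", nrow(x$clusters), nsig))
    print(utils::head(report_clusters(x), 5))
  }
  invisible(x)
}

#' @export
summary.svr_vlsm <- function(object, ...) {
  out <- list(contrast = object$contrast$name,
              n_subjects = length(object$target$y),
              n_voxels = ncol(object$design$X),
              dropped = object$target$dropped,
              clusters = report_clusters(object),
              n_significant = sum(object$clusters$significant),
              beta_range = range(object$voxel$beta),
              scheme = object$scheme, cfg = object$cfg)
  class(out) <- "summary.svr_vlsm"
  out
}

#' @export
print.summary.svr_vlsm <- function(x, ...) {
  cat(sprintf("SVR-VLSM summary — contrast '%s'\n", x$contrast))
  cat(sprintf("  subjects: %d (dropped: %d), voxels tested: %d\n",
              x$n_subjects, length(x$dropped), x$n_voxels))
  cat(sprintf("  beta range: [%.4f, %.4f]\n", x$beta_range[1], x$beta_range[2]))
  cat(sprintf("  significant clusters at FWER %g: %d\n", x$scheme$alpha,
              x$n_significant))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @export
coef.svr_vlsm <- function(object, ...) {
  b <- object$voxel$beta
  names(b) <- apply(object$design$voxel_index, 1, paste, collapse = ",")
  b
}

#' Plot an axial slice of the SVR-VLSM beta map
#'
#' Lesion-coverage-restricted beta values on one axial slice, with
#' significant-cluster voxels outlined by overplotted points.
#'
#' @param x an `svr_vlsm` object.
#' @param slice axial (third-axis) slice index; defaults to the slice with
#'   the most covered voxels.
#' @param ... passed to [graphics::image].
#' @export
plot.svr_vlsm <- function(x, slice = NULL, ...) {
  if (is.null(slice)) {
    counts <- tabulate(x$design$voxel_index[, 3], x$design$dim[3])
    slice <- which.max(counts)
  }
  v <- x$beta_map$values[, , slice]
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v,
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  main = sprintf("SVR-VLSM beta, slice z=%d ('%s')", slice,
                                 x$contrast$name), ...)
  sig <- which(x$cluster_map$values[, , slice] > 0, arr.ind = TRUE)
  if (nrow(sig)) graphics::points(sig[, 1], sig[, 2], pch = 0, cex = 0.8)
  invisible(x)
}

#' @export
print.svr_clsm <- function(x, ...) {
  cat(sprintf("SVR-CLSM: contrast '%s', %d patients, %d edges (disconnection > %.2f)\n",
              x$contrast$name, length(x$target$y), ncol(x$design$X),
              x$design$min_fraction))
  cat(sprintf("  %d permutations, single-step maxT FWER alpha = %g, one-tailed negative\n",
              x$scheme$n_perm, x$scheme$alpha))
  cat(sprintf("  significant edges: %d / %d; significant parcels: %d / %d analyzable\n",
              sum(x$edges$significant), nrow(x$edges),
              sum(x$parcels$significant), sum(x$parcels$analyzable)))
  if (any(x$edges$significant)) {
    sig <- x$edges[x$edges$significant, c("parcel_a", "parcel_b", "beta",
                                          "p_fwer")]
    print(utils::head(sig[order(sig$p_fwer), ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.svr_clsm <- function(object, ...) {
  out <- list(contrast = object$contrast$name,
              n_subjects = length(object$target$y),
              n_edges = nrow(object$edges),
              edges = object$edges[order(object$edges$p_fwer), ],
              parcels = object$parcels,
              n_significant_edges = sum(object$edges$significant),
              n_significant_parcels = sum(object$parcels$significant),
              scheme = object$scheme)
  class(out) <- "summary.svr_clsm"
  out
}

#' @export
print.summary.svr_clsm <- function(x, ...) {
  cat(sprintf("SVR-CLSM summary — contrast '%s'\n", x$contrast))
  cat(sprintf("  subjects: %d, edges tested: %d, significant: %d\n",
              x$n_subjects, x$n_edges, x$n_significant_edges))
  cat("  parcel-level results:\n")
  print(x$parcels, row.names = FALSE)
  invisible(x)
}

#' @export
coef.svr_clsm <- function(object, ...) {
  b <- object$edges$beta
  names(b) <- edge_key(object$edges$parcel_a, object$edges$parcel_b)
  b
}

#' Plot CLSM edge betas against their familywise-corrected p-values
#'
#' @param x an `svr_clsm` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.svr_clsm <- function(x, ...) {
  graphics::plot(x$edges$beta, x$edges$p_fwer,
                 xlab = "edge beta", ylab = "FWER p",
                 main = sprintf("SVR-CLSM edges ('%s')", x$contrast$name),
                 pch = ifelse(x$edges$significant, 19, 1), ...)
  graphics::abline(h = x$scheme$alpha, lty = 2)
  invisible(x)
}
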