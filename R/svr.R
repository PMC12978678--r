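# Core multivariate machinery shared by the voxel- and connectome-level
# pipelines: covariate residualization, SVR fitting with beta-map
# back-projection, and permutation null generation.

#' SVR configuration
#'
#' Hyperparameters of the support vector regression underlying the
#' lesion-symptom maps. The default is a linear epsilon-SVR (C = 0.3,
#' epsilon = 0.1) whose beta map is the exact primal weight vector; results
#' are deterministic given the inputs and `seed`. The default cost was set
#' by power calibration on seeded synthetic cohorts: strong regularization
#' keeps permuted-label fits from absorbing noise, which is what gives the
#' per-feature permutation test its sensitivity (familywise error control
#' holds for any C by construction of the permutation null).
#'
#' With the linear kernel the feature matrix is divided by one global
#' constant (the root-mean-square subject vector norm) before fitting, so
#' `C` and `epsilon` are data-scale-free; feature columns are never
#' individually rescaled, preserving lesion-frequency information.
#'
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param C positive cost parameter.
#' @param epsilon non-negative tube width.
#' @param gamma rbf bandwidth; `"scale"` uses `1/(k * var(X))` as in common
#'   SVM implementations.
#' @param standardize_y scale the (residualized) dependent variable to unit
#'   variance before fitting (default `TRUE`). Lesion features are never
#'   re-standardized: their scale carries lesion-frequency information.
#' @param seed integer seed recorded with results.
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(kernel = c("linear", "rbf"), C = 0.3, epsilon = 0.1,
                       gamma = "scale", standardize_y = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, epsilon >= 0)
  structure(list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
                 standardize_y = isTRUE(standardize_y),
                 seed = as.integer(seed)),
            class = "svr_config")
}

#' Permutation scheme for familywise error control
#'
#' @param n_perm number of permutations (>= 100; the study-scale default is
#'   10,000, simulation work typically uses 500-1,000).
#' @param alpha familywise error level (default 0.05).
#' @param voxel_forming_p voxel-forming threshold for clusterwise correction
#'   (default 0.005, voxel maps only).
#' @param connectivity cluster adjacency: 6 (faces), 18 (+edges), or
#'   26 (+corners, default).
#' @param seed integer; permutation `b` shuffles with seed `seed + b`.
#' @return Object of class `perm_scheme`. The tail is fixed one-sided
#'   negative: damage is coded 1 and higher scores mean better performance,
#'   so deficits manifest as negative beta.
#' @export
perm_scheme <- function(n_perm = 10000L, alpha = 0.05,
                        voxel_forming_p = 0.005, connectivity = 26L,
                        seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stopf("n_perm must be >= 100 for any inference run")
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("connectivity must be 6, 18 or 26")
  stopifnot(alpha > 0, alpha < 1, voxel_forming_p > 0, voxel_forming_p < 1)
  structure(list(n_perm = n_perm, tail = "negative", alpha = alpha,
                 voxel_forming_p = voxel_forming_p,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "perm_scheme")
}

#' Residualize a matrix on covariates
#'
#' Replaces each column of `M` by its least-squares residual after regression
#' on an intercept plus the covariate columns `C`. Applied to both the
#' lesion/edge features and the behavioral target before SVR fitting, so the
#' model sees data orthogonal to lesion volume, age, education and the
#' behavioral control scores.
#'
#' @param M numeric matrix (or vector), subjects in rows.
#' @param C numeric covariate matrix, same row count.
#' @return Matrix (or vector, matching `M`) of residuals; each column is
#'   orthogonal to the intercept and every covariate column within 1e-8.
#' @export
residualize <- function(M, C) {
  vec <- is.null(dim(M))
  M <- as.matrix(M)
  C <- as.matrix(C)
  if (nrow(M) != nrow(C)) stopf("M and C have different row counts")
  n <- nrow(M)
  D <- cbind(`(Intercept)` = 1, C)
  if (ncol(D) + 1 > n + 1)
    stopf("more covariates (+intercept) than subjects")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[-qrD$pivot[seq_len(qrD$rank)]]
    stopf("covariate matrix is rank-deficient; dependent column(s): %s",
          paste(dep, collapse = ", "))
  }
  R <- qr.resid(qrD, M)
  if (vec) drop(R) else R
}

# factor Z (n x n) with Z Z' = X X'; e1071 fitted on Z solves the identical
# dual problem as on X, at O(n^2) per kernel evaluation instead of O(k)
.gram_factor <- function(X) {
  K <- tcrossprod(X)
  e <- eigen(K, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(K))
}

# global feature scale: the linear kernel operates on X/s with
# s = sqrt(mean ||x_i||^2), so the average subject vector has unit norm and
# C/epsilon are data-scale-free (columns are NOT individually rescaled)
.feature_scale <- function(X) {
  s <- sqrt(mean(rowSums(X^2)))
  if (!is.finite(s) || s < 1e-12) 1 else s
}

# dual coefficients (alpha - alpha*) of an eps-SVR fit, full length n
.svr_alpha <- function(fit, n) {
  a <- numeric(n)
  if (length(fit$index)) a[fit$index] <- fit$coefs
  a
}

# libsvm aborts with "Model is empty!" when every residual sits inside the
# epsilon tube (e.g. constant y); the correct solution there is alpha = 0
.svm_fit_alpha <- function(n, ...) {
  fit <- tryCatch(e1071::svm(...), error = function(e) {
    if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
    else stop(e)
  })
  if (is.null(fit)) numeric(n) else .svr_alpha(fit, n)
}

.scale_y <- function(y, cfg) {
  if (cfg$standardize_y) {
    s <- stats::sd(y)
    if (is.finite(s) && s > 1e-12) y <- y / s
  }
  y
}

.rbf_gamma <- function(X, cfg) {
  if (identical(cfg$gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(cfg$gamma)
}

#' Fit an SVR and back-project its beta map
#'
#' Fits epsilon-SVR of `y` on the feature matrix `X` (both already
#' residualized) and returns one beta per feature. With the linear kernel the
#' beta vector is the primal weight vector `t(X) %*% (alpha - alpha*)`,
#' computed exactly via an n x n factorization of the Gram matrix. With the
#' rbf kernel the same dual-coefficient back-projection
#' `beta_j = sum_i alpha_i X_ij` is used as a sensitivity-style map.
#'
#' @param X subjects x features numeric matrix.
#' @param y numeric vector, length `nrow(X)`.
#' @param cfg an [svr_config].
#' @return Numeric beta vector of length `ncol(X)`, with attribute `"alpha"`
#'   (the length-n dual coefficients).
#' @export
fit_svr_beta <- function(X, y, cfg = svr_config()) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stopf("empty design: no features to fit")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stopf("NaN/NA in SVR inputs")
  if (nrow(X) != length(y)) stopf("X rows and y length differ")
  y <- .scale_y(y, cfg)
  n <- nrow(X)
  if (cfg$kernel == "linear") {
    X <- X / .feature_scale(X)
    Z <- .gram_factor(X)
    alpha <- .svm_fit_alpha(n, x = Z, y = y, kernel = "linear",
                            cost = cfg$C, epsilon = cfg$epsilon,
                            type = "eps-regression", scale = FALSE)
  } else {
    alpha <- .svm_fit_alpha(n, x = X, y = y, kernel = "radial",
                            gamma = .rbf_gamma(X, cfg), cost = cfg$C,
                            epsilon = cfg$epsilon, type = "eps-regression",
                            scale = FALSE)
  }
  beta <- drop(crossprod(X, alpha))
  attr(beta, "alpha") <- alpha
  beta
}

#' Permutation null distribution of SVR beta maps
#'
#' Permutation `b` shuffles the (residualized) dependent variable with seed
#' `scheme$seed + b` and refits the SVR; covariates were already removed from
#' both sides, so label shuffling is exchangeable under the null. Featurewise
#' one-tailed (negative) p-values use the add-one rank formula
#' `p_j = (1 + #\{b : beta_j^(b) <= beta_j^obs\}) / (n_perm + 1)`,
#' which never reaches 0.
#'
#' @param X subjects x features residualized matrix.
#' @param y residualized dependent vector.
#' @param cfg an [svr_config].
#' @param scheme a [perm_scheme].
#' @return List: `beta` (observed), `perm_beta` (`n_perm x k` matrix),
#'   `p` (featurewise one-tailed), `scheme`, `cfg`.
#' @export
permutation_null <- function(X, y, cfg = svr_config(), scheme = perm_scheme()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) stopf("NaN/NA in permutation inputs")
  y <- .scale_y(y, cfg)

  if (cfg$kernel == "linear") {
    X <- X / .feature_scale(X)
    Z <- .gram_factor(X)
    fit1 <- function(yy)
      .svm_fit_alpha(n, x = Z, y = yy, kernel = "linear", cost = cfg$C,
                     epsilon = cfg$epsilon, type = "eps-regression",
                     scale = FALSE)
  } else {
    gam <- .rbf_gamma(X, cfg)
    fit1 <- function(yy)
      .svm_fit_alpha(n, x = X, y = yy, kernel = "radial", gamma = gam,
                     cost = cfg$C, epsilon = cfg$epsilon,
                     type = "eps-regression", scale = FALSE)
  }

  alpha_obs <- fit1(y)
  A <- matrix(0, n, scheme$n_perm) # dual coefficients, one column per perm
  for (b in seq_len(scheme$n_perm)) {
    idx <- with_seed(scheme$seed + b, sample.int(n))
    A[, b] <- fit1(y[idx])
  }
  beta_obs <- drop(crossprod(X, alpha_obs))
  perm_beta <- crossprod(A, X) # n_perm x k
  p <- (1 + colSums(sweep(perm_beta, 2, beta_obs, `<=`))) / (scheme$n_perm + 1)
  list(beta = beta_obs, perm_beta = perm_beta, p = p,
       scheme = scheme, cfg = cfg)
}
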