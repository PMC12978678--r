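# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, evaluates `expr`, and restores the caller's
#' RNG state, so seeded generators never perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# cofactor-expansion 3x3 determinant: exact (no LU rounding) for the
# diagonal/orthogonal affines of template space, where voxel volumes must
# reproduce count x volume arithmetic to the last bit
#' @noRd
.det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

#' @noRd
.voxel_volume_mm3 <- function(affine) abs(.det3(affine[1:3, 1:3]))

# affines are equal up to numerical noise from I/O round-trips
#' @noRd
same_affine <- function(a, b, tol = 1e-4) {
  is.matrix(a) && is.matrix(b) && all(dim(a) == c(4, 4)) &&
    all(dim(b) == c(4, 4)) && max(abs(a - b)) <= tol
}
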