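#' Centroid size of a landmark configuration
#'
#' The standard size measure of geometric morphometrics: the square root of
#' the summed squared distances of all landmarks from their centroid.
#' Homogeneous of degree 1 (scaling the configuration by k scales CS by k).
#'
#' @param config a `landmark_config` or a p x 3 coordinate matrix.
#' @return positive scalar; 0 (with a warning) if all points coincide.
#' @export
centroid_size <- function(config) {
  X <- coords_of(config)
  if (nrow(X) < 2L) stop("centroid size needs at least 2 points")
  Xc <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(Xc^2))
  if (cs == 0) warning("degenerate configuration: all points coincident")
  cs
}

## Center a coordinate matrix on its centroid.
center_coords <- function(X) sweep(X, 2, colMeans(X))

#' Optimal rotation between two centered point sets
#'
#' Finds the proper rotation R (det = +1, reflections excluded) minimizing
#' `||A %*% R - B||^2` for homologous, centered point sets A and B
#' (Kabsch/Procrustes solution via SVD of the cross-covariance).  When the
#' cross-covariance is rank deficient the singular vector of the smallest
#' singular value is flipped to enforce a proper rotation, a deterministic
#' tie-break.
#'
#' @param A,B p x 3 centered coordinate matrices.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("point sets must match in dimension")
  s <- svd(crossprod(A, B))        # A'B = U D V'
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## Canonical orientation: rotate a set of aligned configurations so the
## consensus sits in its principal-axes frame with deterministic signs.
## Makes GPA output invariant to rigid pre-transformation of the inputs and
## to input order (up to numerical noise).
canonical_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(consensus %*% V[, j]))
    if ((consensus %*% V[, j])[i] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Generalized Procrustes analysis (partial Procrustes)
#'
#' Iterative superimposition of homologous configurations: each is centered
#' and scaled to unit centroid size once, then repeatedly rotated to the
#' current consensus (pointwise mean), which is updated until it moves less
#' than `tol` (Frobenius norm) or `max_iter` is reached.  Scale is fixed at
#' unit centroid size (partial Procrustes): no per-iteration scale
#' re-optimization.  The result is rotated into a canonical principal-axes
#' frame so it does not depend on the orientation of any input or on input
#' order.
#'
#' @param configs list of `landmark_config` objects (>= 2, same element type)
#'   or of p x 3 matrices.
#' @param tol convergence tolerance on the consensus shift (default 1e-10).
#' @param max_iter maximum iterations (default 100).
#' @return an object of class `gpa_result` with elements `aligned` (list of
#'   p x 3 matrices, centered, unit centroid size), `consensus` (pointwise
#'   mean of the aligned configurations), `centroid_sizes`,
#'   `log_centroid_sizes`, `specimen_ids`, `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L)
    stop("generalized Procrustes analysis needs at least 2 configurations")
  is_cfg <- all(vapply(configs, is_landmark_config, logical(1)))
  if (is_cfg) check_homologous(configs)
  ids <- if (is_cfg)
    vapply(configs, `[[`, character(1), "specimen_id")
  else if (!is.null(names(configs))) names(configs)
  else paste0("spec", seq_along(configs))
  X <- lapply(configs, coords_of)
  p <- unique(vapply(X, nrow, integer(1)))
  if (length(p) != 1L) stop("configurations have differing point counts")

  cs <- vapply(X, centroid_size, numeric(1))
  if (any(cs == 0)) stop("degenerate configuration with zero centroid size")
  X <- lapply(seq_along(X), function(i) center_coords(X[[i]]) / cs[i])

  consensus <- Reduce(`+`, X) / length(X)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    X <- lapply(X, function(A) A %*% optimal_rotation(A, consensus))
    new_consensus <- Reduce(`+`, X) / length(X)
    shift <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (shift < tol) { converged <- TRUE; break }
  }
  V <- canonical_rotation(consensus)
  X <- lapply(X, function(A) A %*% V)
  consensus <- consensus %*% V
  names(X) <- ids
  structure(list(aligned = X, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, ids),
                 log_centroid_sizes = stats::setNames(log(cs), ids),
                 specimen_ids = ids,
                 iterations = it, converged = converged),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf(
    "<gpa_result> %d specimens, %d landmarks, %d iterations (%s)\n",
    length(x$aligned), nrow(x$consensus), x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' Centers and scales both to unit centroid size, rotates the first onto the
#' second, and returns the root summed squared difference.
#'
#' @param a,b configurations or p x 3 matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  A <- center_coords(coords_of(a)); A <- A / sqrt(sum(A^2))
  B <- center_coords(coords_of(b)); B <- B / sqrt(sum(B^2))
  A <- A %*% optimal_rotation(A, B)
  sqrt(sum((A - B)^2))
}
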