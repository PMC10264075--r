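#' Fit a 3D thin-plate spline between homologous point sets
#'
#' Interpolating deformation from `source` to `target` using the 3D
#' biharmonic kernel U(r) = r with affine terms \{1, x, y, z\}.  The warp maps
#' every source landmark exactly onto its target; the non-affine weights
#' satisfy the usual side conditions (orthogonality to constants and to the
#' source coordinates).  The bending energy is the roughness of the
#' non-affine part: since the Euclidean-distance kernel is conditionally
#' negative definite in 3D, the non-negative quadratic form is
#' `-sum over output dims of w' K w`, which is 0 exactly when the target is
#' an affine image of the source.
#'
#' @param source,target p x 3 matrices of homologous landmarks; source points
#'   must be distinct (duplicates make the kernel system singular).
#' @return an object of class `tps_model` with `source`, `target`, `weights`
#'   (p x 3 non-affine weights), `affine` (4 x 3: intercept row + 3 x 3
#'   linear part), and `bending_energy`.
#' @export
tps_fit <- function(source, target) {
  S <- as.matrix(source); Tt <- as.matrix(target)
  if (!all(dim(S) == dim(Tt))) stop("source and target must match in size")
  if (ncol(S) != 3L) stop("thin-plate spline is implemented for 3D points")
  p <- nrow(S)
  if (p < 5L) stop("need at least 5 landmarks to fit a 3D spline")
  D <- as.matrix(stats::dist(S))
  if (any(D[upper.tri(D)] == 0)) {
    dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
    stop("duplicated source points make the spline singular: rows ",
         paste(unique(c(dup)), collapse = ", "))
  }
  P <- cbind(1, S)
  L <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Tt, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs),
                  error = function(e) stop("singular spline system: ",
                                           conditionMessage(e)))
  W <- sol[seq_len(p), , drop = FALSE]
  A <- sol[p + 1:4, , drop = FALSE]
  be <- -sum(W * (D %*% W))      # = -sum_dims w'Kw >= 0 (U(r)=r is CND)
  structure(list(source = S, target = Tt, weights = W, affine = A,
                 bending_energy = max(be, 0)),
            class = "tps_model")
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("<tps_model> %d landmarks, bending energy %.6g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Evaluate a fitted thin-plate spline at arbitrary points
#'
#' @param model a `tps_model` from [tps_fit()].
#' @param points q x 3 matrix of query points.
#' @return q x 3 matrix of warped points.
#' @export
tps_warp <- function(model, points) {
  stopifnot(inherits(model, "tps_model"))
  Q <- as.matrix(points)
  if (ncol(Q) != 3L) stop("points must be q x 3")
  ## pairwise distances query -> source landmarks
  K <- sqrt(pmax(outer(rowSums(Q^2), rowSums(model$source^2), `+`) -
                   2 * tcrossprod(Q, model$source), 0))
  cbind(1, Q) %*% model$affine + K %*% model$weights
}

#' Bending-energy matrix of a reference configuration
#'
#' The p x p positive semidefinite matrix E such that the bending energy of
#' the spline carrying `reference` onto any target Y equals
#' `sum over dims of y_d' E y_d`.  E is the negated upper-left p x p block of
#' the inverse of the bordered kernel system (negated because U(r) = r is
#' conditionally negative definite in 3D); its null space contains all affine
#' images of the reference.  This matrix drives semilandmark sliding.
#'
#' @param reference p x 3 matrix (or `landmark_config`).
#' @return p x p symmetric PSD matrix.
#' @export
bending_energy_matrix <- function(reference) {
  S <- coords_of(reference)
  p <- nrow(S)
  D <- as.matrix(stats::dist(S))
  P <- cbind(1, S)
  L <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  Li <- solve(L)
  E <- -Li[seq_len(p), seq_len(p), drop = FALSE]
  (E + t(E)) / 2
}

## Total bending energy of reference -> config under a precomputed E matrix.
bending_energy_quad <- function(E, Y) {
  Y <- coords_of(Y)
  max(sum(Y * (E %*% Y)), 0)
}
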