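#' Principal component analysis of superimposed shapes
#'
#' Eigen-analysis (via SVD) of the covariance of the flattened, mean-centered
#' aligned coordinates of a [gpa()] result.  Components are capped at
#' `min(n - 1, 3p)` and components with (numerically) zero variance are
#' dropped.  Each loading is oriented so that its largest-magnitude element
#' is positive, making signs deterministic.
#'
#' @param gpa_result a `gpa_result` (needs >= 3 specimens).
#' @return object of class `shape_pca`: `scores` (n x k, column-centered),
#'   `loadings` (3p x k, orthonormal), `variance_fraction` (sums to 1 over
#'   the retained components), `sdev`, `mean_flat` (flattened consensus,
#'   x1 y1 z1 x2 ...), `n_points`, `specimen_ids`.
#' @export
shape_pca <- function(gpa_result) {
  stopifnot(inherits(gpa_result, "gpa_result"))
  n <- length(gpa_result$aligned)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  X <- t(vapply(gpa_result$aligned, function(A) as.vector(t(A)),
                numeric(3L * nrow(gpa_result$consensus))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = min(n, ncol(Xc)), nv = min(n, ncol(Xc)))
  kmax <- min(n - 1L, ncol(Xc))
  d <- s$d[seq_len(kmax)]
  keep <- d > max(d) * 1e-10
  d <- d[keep]
  V <- s$v[, seq_len(kmax), drop = FALSE][, keep, drop = FALSE]
  ## deterministic sign: largest-magnitude loading element positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(scores) <- gpa_result$specimen_ids
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  varfrac <- d^2 / sum(d^2)
  structure(list(scores = scores, loadings = V,
                 variance_fraction = varfrac,
                 sdev = d / sqrt(n - 1),
                 mean_flat = mu, n_points = nrow(gpa_result$consensus),
                 specimen_ids = gpa_result$specimen_ids),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat(sprintf("<shape_pca> %d specimens, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance: ",
      paste(sprintf("%s %.1f%%", colnames(x$scores)[1:k],
                    100 * x$variance_fraction[1:k]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## Refold a flattened (x1 y1 z1 x2 ...) shape vector into p x 3.
refold_shape <- function(flat) matrix(flat, ncol = 3, byrow = TRUE)
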