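#' Triangle mesh
#'
#' Minimal triangle-mesh container standing in for digitized bone surfaces.
#' Faces are 1-based vertex index triples.  Degenerate (zero-area) faces are
#' dropped at construction; watertightness is not required.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @return object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces) {
  V <- as.matrix(vertices); storage.mode(V) <- "double"
  Fc <- as.matrix(faces); storage.mode(Fc) <- "integer"
  if (ncol(V) != 3L) stop("vertices must be n x 3")
  if (ncol(Fc) != 3L) stop("faces must be m x 3 index triples")
  if (nrow(Fc) && (min(Fc) < 1L || max(Fc) > nrow(V)))
    stop("face indices out of range")
  if (nrow(Fc)) {
    a <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
    b <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    keep <- area2 > 0
    if (!all(keep)) Fc <- Fc[keep, , drop = FALSE]
  }
  structure(list(vertices = V, faces = Fc), class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

## Area-weighted vertex normals (unnormalized face normals accumulated at
## their corners, then unit-normalized).
vertex_normals <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  a <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])   # magnitude = 2*area
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    agg <- rowsum(fn, group = Fc[, k])
    ids <- as.integer(rownames(agg))
    N[ids, ] <- N[ids, ] + agg
  }
  nrm <- sqrt(rowSums(N^2))
  nrm[nrm == 0] <- 1
  N / nrm
}

#' Closest points on a triangle mesh
#'
#' For each query point, the nearest point on any triangle of the mesh
#' (vectorized Ericson closest-point-on-triangle over all faces), with the
#' face index and an interpolated (area-weighted vertex-normal) surface
#' normal at the foot point.
#'
#' @param mesh a `bone_mesh`.
#' @param points q x 3 matrix.
#' @param k_candidates number of nearest faces (by centroid, padded by the
#'   largest face circumradius) among which the exact closest point is
#'   computed.  The default is exact for meshes whose faces are small
#'   relative to their spacing, which holds for the surface meshes used
#'   here.
#' @return list with `points` (q x 3 projected), `face` (q face indices),
#'   `normal` (q x 3 unit normals), `distance` (q).
#' @export
closest_point_mesh <- function(mesh, points, k_candidates = 48L) {
  Q <- as.matrix(points)
  if (!nrow(mesh$faces)) stop("empty mesh")
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  VN <- vertex_normals(mesh)
  nf <- nrow(Fc)
  cent <- (A + B + C) / 3
  ## prefilter: squared distances query -> face centroids (q x nf), keep
  ## the k nearest candidates per query (always exact when k >= nf)
  k <- min(as.integer(k_candidates), nf)
  D2 <- outer(rowSums(Q^2), rowSums(cent^2), `+`) - 2 * tcrossprod(Q, cent)
  out_p <- matrix(0, nrow(Q), 3)
  out_f <- integer(nrow(Q)); out_d <- numeric(nrow(Q))
  out_n <- matrix(0, nrow(Q), 3)
  for (i in seq_len(nrow(Q))) {
    cand <- if (k < nf) order(D2[i, ])[seq_len(k)] else seq_len(nf)
    cp <- closest_on_triangles(Q[i, ], A[cand, , drop = FALSE],
                               ab[cand, , drop = FALSE],
                               ac[cand, , drop = FALSE])
    d2 <- rowSums(sweep(cp$point, 2, Q[i, ])^2)
    jj <- which.min(d2)
    j <- cand[jj]
    out_p[i, ] <- cp$point[jj, ]
    out_f[i] <- j
    out_d[i] <- sqrt(d2[jj])
    w <- c(1 - cp$u[jj] - cp$v[jj], cp$u[jj], cp$v[jj])
    n <- w[1] * VN[Fc[j, 1], ] + w[2] * VN[Fc[j, 2], ] + w[3] * VN[Fc[j, 3], ]
    nn <- sqrt(sum(n^2)); if (nn == 0) { n <- c(0, 0, 1); nn <- 1 }
    out_n[i, ] <- n / nn
  }
  list(points = out_p, face = out_f, normal = out_n, distance = out_d)
}

## Closest point of one query point q on every triangle (A, A+ab, A+ac),
## vectorized over triangles.  Returns barycentric (u,v) of the foot point.
closest_on_triangles <- function(q, A, ab, ac) {
  ap <- sweep(-A, 2, q, `+`)              # q - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- ap - ab                            # q - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- ap - ac                           # q - C
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  u <- rep(0, nrow(A)); v <- rep(0, nrow(A))
  ## interior case
  denom <- va + vb + vc
  ok <- denom != 0
  u[ok] <- vb[ok] / denom[ok]; v[ok] <- vc[ok] / denom[ok]
  ## vertex regions
  regA <- d1 <= 0 & d2 <= 0
  regB <- d3 >= 0 & d4 <= d3
  regC <- d6 >= 0 & d5 <= d6
  ## edge regions
  t_ab <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  regAB <- vc <= 0 & d1 >= 0 & d3 <= 0
  t_ac <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  regAC <- vb <= 0 & d2 >= 0 & d6 <= 0
  t_bc <- ifelse((d4 - d3) + (d5 - d6) != 0,
                 (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  regBC <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  u[regBC] <- 1 - t_bc[regBC]; v[regBC] <- t_bc[regBC]
  u[regAC] <- 0; v[regAC] <- t_ac[regAC]
  u[regAB] <- t_ab[regAB]; v[regAB] <- 0
  u[regC] <- 0; v[regC] <- 1
  u[regB] <- 1; v[regB] <- 0
  u[regA] <- 0; v[regA] <- 0
  u <- pmin(pmax(u, 0), 1); v <- pmin(pmax(v, 0), 1)
  s <- u + v; over <- s > 1
  u[over] <- u[over] / s[over]; v[over] <- v[over] / s[over]
  list(point = A + ab * u + ac * v, u = u, v = v)
}
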