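## Closest point on a polyline for each query point (vectorized over
## segments).  Returns the projected coordinates.
project_polyline <- function(points, poly) {
  Q <- as.matrix(points)
  A <- poly[-nrow(poly), , drop = FALSE]
  B <- poly[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1
  out <- matrix(0, nrow(Q), 3)
  for (i in seq_len(nrow(Q))) {
    t <- pmin(pmax(rowSums(sweep(-A, 2, Q[i, ], `+`) * AB) / len2, 0), 1)
    P <- A + AB * t
    d2 <- rowSums(sweep(P, 2, Q[i, ])^2)
    out[i, ] <- P[which.min(d2), ]
  }
  out
}

## Deterministic orthonormal tangent pair perpendicular to a unit normal.
tangent_basis <- function(n) {
  a <- c(0, 0, 0); a[which.min(abs(n))] <- 1
  t1 <- pracma_cross(n, a); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- pracma_cross(n, t1)
  rbind(t1, t2)
}

## Sliding directions for every semilandmark of `config`.
## Curve semilandmarks: one direction, the central difference of their curve
## neighbours (anchors included in the path).  Surface semilandmarks: two
## orthonormal tangents from the mesh normal at the nearest surface point
## when a mesh is supplied, otherwise from a local plane fit of patch
## neighbours.  Returns parallel vectors idx (point index, repeated for
## 2-dof points) and dirs (unit direction rows), plus per-curve polylines
## for re-projection.
sliding_tangents <- function(config, template, specimen_mesh = NULL) {
  Y <- config$points
  idx <- integer(0)
  dirs <- matrix(0, 0, 3)
  for (path in template$curves) {
    inner <- path[-c(1, length(path))]
    for (k in seq_along(inner)) {
      i <- inner[k]
      tv <- Y[path[k + 2], ] - Y[path[k], ]   # neighbours in path order
      nn <- sqrt(sum(tv^2))
      if (nn == 0) next                        # degenerate: hold fixed
      idx <- c(idx, i)
      dirs <- rbind(dirs, tv / nn)
    }
  }
  surf <- unlist(template$patches, use.names = FALSE)
  if (length(surf)) {
    if (!is.null(specimen_mesh)) {
      cp <- closest_point_mesh(specimen_mesh, Y[surf, , drop = FALSE])
      for (k in seq_along(surf)) {
        tb <- tangent_basis(cp$normal[k, ])
        idx <- c(idx, surf[k], surf[k])
        dirs <- rbind(dirs, tb)
      }
    } else {
      ## Landmark-only data: tangent plane from a local plane fit of patch
      ## neighbours.  Neighbour sets are determined once from the template
      ## geometry (the fixed-topology analogue of a mesh), so the sliding
      ## directions vary smoothly across specimens instead of jumping with
      ## each specimen's noise.
      tpl_pts <- template$template_config$points
      for (patch in template$patches) {
        if (length(patch) < 3L) {
          warning("patch with fewer than 3 points: semilandmarks held fixed")
          next
        }
        P <- Y[patch, , drop = FALSE]
        Pt <- tpl_pts[patch, , drop = FALSE]
        for (k in seq_along(patch)) {
          d2 <- rowSums(sweep(Pt, 2, Pt[k, ])^2)
          nb <- order(d2)[seq_len(min(12L, length(patch)))]
          C <- P[nb, , drop = FALSE]
          C <- sweep(C, 2, colMeans(C))
          e <- eigen(crossprod(C), symmetric = TRUE)
          n <- e$vectors[, 3]
          tb <- tangent_basis(n / sqrt(sum(n^2)))
          idx <- c(idx, patch[k], patch[k])
          dirs <- rbind(dirs, tb)
        }
      }
    }
  }
  list(idx = idx, dirs = dirs)
}

#' One bending-energy sliding iteration
#'
#' Moves every semilandmark of `config` along its permitted tangent
#' direction(s) — curve points along their local curve tangent, surface
#' points within their local tangent plane — by the displacement that
#' minimizes the thin-plate-spline bending energy of the deformation from
#' `reference` to the updated configuration (generalized-least-squares
#' sliding).  Anatomical landmarks never move.  After sliding, curve
#' semilandmarks are re-projected onto their (pre-slide) curve polyline, and
#' surface semilandmarks onto the specimen mesh when one is supplied;
#' without a mesh the tangent-plane positions are kept.  A step-halving
#' safeguard rejects any update that would increase the bending energy, so
#' the objective is non-increasing.
#'
#' @param config `landmark_config` to relax.
#' @param reference reference configuration (template or consensus).
#' @param template `template_definition` (curve paths, patches).
#' @param specimen_mesh optional `bone_mesh` of the specimen surface.
#' @param E optional precomputed [bending_energy_matrix()] of `reference`.
#' @param ridge small ridge added to the sliding normal equations.
#' @return the updated `landmark_config`, with attribute `bending_energy`.
#' @export
slide_iteration <- function(config, reference, template,
                            specimen_mesh = NULL, E = NULL,
                            ridge = 1e-10) {
  stopifnot(is_landmark_config(config))
  refX <- coords_of(reference)
  if (is.null(E)) E <- bending_energy_matrix(refX)
  Y0 <- config$points
  tg <- sliding_tangents(config, template, specimen_mesh)
  be0 <- bending_energy_quad(E, Y0)
  if (!length(tg$idx)) {
    attr(config, "bending_energy") <- be0
    return(config)
  }
  EY <- E %*% Y0
  M <- E[tg$idx, tg$idx, drop = FALSE] * tcrossprod(tg$dirs)
  rhs <- -rowSums(tg$dirs * EY[tg$idx, , drop = FALSE])
  sc <- mean(diag(M)); if (!is.finite(sc) || sc <= 0) sc <- 1
  t_full <- solve(M + ridge * sc * diag(length(tg$idx)), rhs)

  ## pre-slide polylines per curve (re-projection targets)
  polys <- lapply(template$curves, function(path) Y0[path, , drop = FALSE])

  step <- 1
  for (h in 0:30) {
    disp <- rowsum(tg$dirs * (step * t_full), tg$idx)
    rows <- as.integer(rownames(disp))
    Y1 <- Y0
    Y1[rows, ] <- Y1[rows, ] + disp
    ## re-project curve semilandmarks onto their polyline
    for (ci in seq_along(template$curves)) {
      path <- template$curves[[ci]]
      inner <- path[-c(1, length(path))]
      Y1[inner, ] <- project_polyline(Y1[inner, , drop = FALSE], polys[[ci]])
    }
    ## re-project surface semilandmarks onto the mesh
    if (!is.null(specimen_mesh)) {
      surf <- unlist(template$patches, use.names = FALSE)
      if (length(surf))
        Y1[surf, ] <- closest_point_mesh(specimen_mesh,
                                         Y1[surf, , drop = FALSE])$points
    }
    be1 <- bending_energy_quad(E, Y1)
    if (be1 <= be0 + 1e-12 * max(1, be0)) {
      config$points <- Y1
      attr(config, "bending_energy") <- be1
      return(config)
    }
    step <- step / 2
  }
  attr(config, "bending_energy") <- be0   # no acceptable step: hold position
  config
}

#' Relax configurations toward the template
#'
#' Runs `n_iter` bending-energy sliding iterations per specimen with the
#' template configuration as the fixed reference (default 5 iterations, the
#' standard protocol for homogenizing semilandmark placement against a
#' template).
#'
#' @param configs list of `landmark_config` objects homologous with the
#'   template.
#' @param template `template_definition`.
#' @param n_iter number of sliding iterations (>= 0).
#' @param meshes optional list of per-specimen `bone_mesh` surfaces.
#' @return object of class `sliding_result`: `configs` (relaxed),
#'   `bending_energy_trace` (total energy before sliding and after each
#'   iteration; non-increasing), `iterations_run`.
#' @export
relax_to_template <- function(configs, template, n_iter = 5L,
                              meshes = NULL) {
  if (n_iter < 0) stop("n_iter must be non-negative")
  if (is_landmark_config(configs)) configs <- list(configs)
  ref <- template$template_config
  E <- bending_energy_matrix(ref)
  trace <- sum(vapply(configs, function(cc)
    bending_energy_quad(E, cc$points), numeric(1)))
  if (n_iter > 0) for (it in seq_len(n_iter)) {
    configs <- lapply(seq_along(configs), function(i)
      slide_iteration(configs[[i]], ref, template,
                      specimen_mesh = if (is.null(meshes)) NULL else meshes[[i]],
                      E = E))
    trace <- c(trace, sum(vapply(configs, attr, numeric(1),
                                 "bending_energy")))
  }
  structure(list(configs = configs, bending_energy_trace = trace,
                 iterations_run = as.integer(n_iter)),
            class = "sliding_result")
}

#' Relax configurations toward their Procrustes consensus
#'
#' Computes the partial-Procrustes consensus of the configurations once and
#' uses it as the fixed sliding reference for `n_iter` iterations (default
#' 2, the finishing step of the relaxation protocol).  Set
#' `recompute_consensus = TRUE` to refresh the consensus before every
#' iteration instead; the fixed-target default keeps the bending-energy
#' trace provably non-increasing.
#'
#' @inheritParams relax_to_template
#' @param recompute_consensus refresh the consensus each iteration?
#' @return a `sliding_result` (see [relax_to_template()]), plus `consensus`.
#' @export
relax_to_consensus <- function(configs, template, n_iter = 2L,
                               meshes = NULL, recompute_consensus = FALSE) {
  if (n_iter < 0) stop("n_iter must be non-negative")
  if (length(configs) < 2L)
    stop("consensus relaxation needs at least 2 configurations")
  consensus <- gpa(configs)$consensus
  E <- bending_energy_matrix(consensus)
  trace <- sum(vapply(configs, function(cc)
    bending_energy_quad(E, cc$points), numeric(1)))
  if (n_iter > 0) for (it in seq_len(n_iter)) {
    if (recompute_consensus && it > 1L) {
      consensus <- gpa(configs)$consensus
      E <- bending_energy_matrix(consensus)
    }
    configs <- lapply(seq_along(configs), function(i)
      slide_iteration(configs[[i]], consensus, template,
                      specimen_mesh = if (is.null(meshes)) NULL else meshes[[i]],
                      E = E))
    trace <- c(trace, sum(vapply(configs, attr, numeric(1),
                                 "bending_energy")))
  }
  structure(list(configs = configs, bending_energy_trace = trace,
                 iterations_run = as.integer(n_iter),
                 consensus = consensus),
            class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  tr <- x$bending_energy_trace
  cat(sprintf("<sliding_result> %d configs, %d iterations, energy %.6g -> %.6g\n",
              length(x$configs), x$iterations_run, tr[1], tr[length(tr)]))
  invisible(x)
}

#' Project template surface semilandmarks onto a specimen mesh
#'
#' Fits a thin-plate spline from the template's fixed (anatomical and
#' curve) landmarks to the specimen's fixed landmarks, warps the template's
#' surface semilandmarks with it, and replaces each warped point by its
#' closest point on the specimen mesh.  This transfers the template's
#' surface patch onto a specimen on which only anatomical landmarks and
#' curves were digitized.
#'
#' @param template `template_definition` (must include surface patches).
#' @param specimen_mesh `bone_mesh` of the specimen.
#' @param specimen_fixed `landmark_config` or matrix of the specimen's fixed
#'   (anatomical + curve) landmarks, ordered as in the template.
#' @param snap_radius warn when warped points land farther than this from
#'   the mesh (default: a tenth of the mesh bounding-box diagonal).
#' @return a full `landmark_config` for the specimen (template ordering).
#' @export
project_patch <- function(template, specimen_mesh, specimen_fixed,
                          snap_radius = NULL) {
  stopifnot(inherits(template, "template_definition"),
            inherits(specimen_mesh, "bone_mesh"))
  if (!nrow(specimen_mesh$faces)) stop("empty mesh")
  tc <- template$template_config
  fixed_idx <- which(tc$classes != "surface_semi")
  surf_idx <- which(tc$classes == "surface_semi")
  Xf <- coords_of(specimen_fixed)
  if (nrow(Xf) != length(fixed_idx))
    stop("specimen_fixed must have ", length(fixed_idx),
         " points (anatomical + curve), got ", nrow(Xf))
  model <- tps_fit(tc$points[fixed_idx, , drop = FALSE], Xf)
  warped <- tps_warp(model, tc$points[surf_idx, , drop = FALSE])
  snapped <- closest_point_mesh(specimen_mesh, warped)
  if (is.null(snap_radius)) {
    bb <- apply(specimen_mesh$vertices, 2, range)
    snap_radius <- 0.1 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  }
  n_far <- sum(snapped$distance > snap_radius)
  if (n_far > 0)
    warning(n_far, " warped surface point(s) farther than the snap radius ",
            "from the mesh")
  P <- matrix(0, nrow(tc$points), 3)
  P[fixed_idx, ] <- Xf
  P[surf_idx, ] <- snapped$points
  id <- if (is_landmark_config(specimen_fixed))
    specimen_fixed$specimen_id else "specimen"
  side <- if (is_landmark_config(specimen_fixed))
    specimen_fixed$side else tc$side
  landmark_config(P, tc$classes, specimen_id = id, element = tc$element,
                  side = side, group = tc$group)
}
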