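#' Warp the template mesh onto the Procrustes consensus
#'
#' Fits a thin-plate spline from the template landmark configuration to the
#' consensus shape of a [gpa()] result and warps every template mesh vertex
#' with it, yielding a "consensual" mesh representing the mean shape of the
#' sample.
#'
#' @param template `template_definition` with a mesh.
#' @param gpa_result a `gpa_result` whose consensus is homologous with the
#'   template configuration.
#' @return a `bone_mesh` (warped copy of the template mesh).
#' @export
consensus_mesh <- function(template, gpa_result) {
  stopifnot(inherits(template, "template_definition"))
  if (is.null(template$template_mesh))
    stop("template has no mesh to warp")
  target <- if (inherits(gpa_result, "gpa_result"))
    gpa_result$consensus else as.matrix(gpa_result)
  model <- tps_fit(template$template_config$points, target)
  bone_mesh(tps_warp(model, template$template_mesh$vertices),
            template$template_mesh$faces)
}

#' Mean shapes per mixture cluster along one PC axis
#'
#' Reconstructs the mean landmark configuration of each mixture cluster by
#' displacing the consensus along the chosen PC loading by the cluster's
#' mean score (scores on the other axes are set to zero, so the
#' reconstruction isolates the variation carried by the dimorphic axis; set
#' `full_space = TRUE` to use the clusters' full mean score vectors
#' instead).  Optionally warps the template mesh onto each cluster mean.
#'
#' @param pca a `shape_pca`.
#' @param gmm a `gmm_result` fitted on the scores of `axis` (needs
#'   `selected_G >= 2`).
#' @param axis PC index the mixture was fitted on.
#' @param template optional `template_definition` with mesh; when given,
#'   each cluster also gets a warped mesh.
#' @param full_space reconstruct from all axes' cluster mean scores?
#' @return object of class `cluster_shapes`: per-cluster list with
#'   `mean_scores`, `shape` (p x 3), optional `mesh`; plus `consensus`.
#' @export
cluster_mean_shapes <- function(pca, gmm, axis = 1L, template = NULL,
                                full_space = FALSE) {
  stopifnot(inherits(pca, "shape_pca"), inherits(gmm, "gmm_result"))
  if (gmm$selected_G < 2L)
    stop("cluster shapes need a mixture with at least 2 components")
  z <- gmm$assignments
  if (length(z) != nrow(pca$scores))
    stop("assignment length does not match the score matrix")
  clusters <- sort(unique(z))
  shapes <- lapply(clusters, function(g) {
    in_g <- z == g
    if (!any(in_g)) stop("empty cluster: ", g)
    if (full_space) {
      sbar <- colMeans(pca$scores[in_g, , drop = FALSE])
      flat <- pca$mean_flat + as.vector(pca$loadings %*% sbar)
    } else {
      sbar <- mean(pca$scores[in_g, axis])
      flat <- pca$mean_flat + sbar * pca$loadings[, axis]
    }
    out <- list(mean_score = if (full_space) sbar else sbar,
                shape = refold_shape(flat))
    if (!is.null(template) && !is.null(template$template_mesh))
      out$mesh <- consensus_mesh(template, out$shape)
    out
  })
  names(shapes) <- paste0("cluster", clusters)
  structure(list(clusters = shapes, axis = axis,
                 consensus = refold_shape(pca$mean_flat),
                 full_space = full_space),
            class = "cluster_shapes")
}

#' @export
print.cluster_shapes <- function(x, ...) {
  cat(sprintf("<cluster_shapes> %d clusters along PC%d%s\n",
              length(x$clusters), x$axis,
              if (x$full_space) " (full-space reconstruction)" else ""))
  invisible(x)
}

#' Export reconstructed cluster shapes
#'
#' Writes each cluster's mean landmark configuration as CSV and, when a mesh
#' was reconstructed, as an ASCII PLY.
#'
#' @param shapes a `cluster_shapes`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
export_cluster_shapes <- function(shapes, dir) {
  stopifnot(inherits(shapes, "cluster_shapes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(shapes$clusters)) {
    cl <- shapes$clusters[[nm]]
    csv <- file.path(dir, paste0(nm, "_landmarks.csv"))
    utils::write.csv(data.frame(point = seq_len(nrow(cl$shape)),
                                x = cl$shape[, 1], y = cl$shape[, 2],
                                z = cl$shape[, 3]),
                     csv, row.names = FALSE)
    paths <- c(paths, csv)
    if (!is.null(cl$mesh)) {
      ply <- file.path(dir, paste0(nm, ".ply"))
      write_mesh(cl$mesh, ply)
      paths <- c(paths, ply)
    }
  }
  invisible(paths)
}
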