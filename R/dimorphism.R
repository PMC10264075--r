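#' Allometry test: Pearson correlation of scores with log centroid size
#'
#' Size-related shape variation (allometry) is tested per PC axis as the
#' Pearson correlation between the axis scores and the natural log of
#' centroid size, with the usual two-sided t-based p-value
#' (`stats::cor.test`).  A non-significant correlation on a dimorphic axis
#' indicates that the dimorphism is size independent.
#'
#' @param scores numeric vector of per-specimen PC scores.
#' @param log_cs numeric vector of log centroid sizes (same length, n >= 3).
#' @return object of class `allometry_result`: `r`, `p_value`, `n`.
#' @export
allometry_test <- function(scores, log_cs) {
  if (length(scores) != length(log_cs))
    stop("scores and log_cs must have the same length")
  if (length(scores) < 3L) stop("allometry test needs n >= 3")
  if (stats::sd(scores) == 0 || stats::sd(log_cs) == 0)
    stop("degenerate variance: constant input")
  ct <- stats::cor.test(scores, log_cs, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(scores)),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("<allometry_result> r = %.3f, p = %.4g, n = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Scan PC axes for size-independent dimorphism
#'
#' For each requested axis, fits a univariate Gaussian mixture to the PC
#' scores ([fit_gmm_1d()]) and tests allometry against the log centroid
#' sizes ([allometry_test()]).  An axis is flagged "dimorphic,
#' size-independent" when the mixture selects exactly two components and the
#' allometry p-value exceeds `alpha`.
#'
#' @param pca a `shape_pca`.
#' @param gpa_result the matching `gpa_result` (provides centroid sizes).
#' @param axes integer PC indices to scan (default 1:5, capped at the
#'   available components).
#' @param G_max mixture component search limit.
#' @param alpha allometry significance threshold (default 0.05); an axis
#'   whose scores correlate with size at p < alpha is never flagged.
#' @param p_adjust optional multiple-testing correction for the allometry
#'   p-values across the scanned axes (`"none"`, default, or any
#'   `stats::p.adjust` method such as `"BH"`).
#' @return object of class `dimorphism_scan`: per-axis list with `gmm`,
#'   `allometry`, `dimorphic`, plus a `summary` data frame.
#' @export
dimorphism_scan <- function(pca, gpa_result, axes = 1:5, G_max = 9L,
                            alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(pca, "shape_pca"), inherits(gpa_result, "gpa_result"))
  axes <- as.integer(axes)
  axes <- axes[axes >= 1L & axes <= ncol(pca$scores)]
  if (!length(axes)) stop("no valid axes to scan")
  log_cs <- gpa_result$log_centroid_sizes[pca$specimen_ids]
  per_axis <- lapply(axes, function(a) {
    sc <- pca$scores[, a]
    list(axis = a,
         gmm = fit_gmm_1d(sc, G_max = G_max),
         allometry = allometry_test(sc, log_cs))
  })
  names(per_axis) <- paste0("PC", axes)
  praw <- vapply(per_axis, function(z) z$allometry$p_value, numeric(1))
  padj <- stats::p.adjust(praw, method = p_adjust)
  for (i in seq_along(per_axis)) {
    per_axis[[i]]$allometry_p_adjusted <- padj[i]
    per_axis[[i]]$dimorphic <-
      per_axis[[i]]$gmm$selected_G == 2L && padj[i] > alpha
  }
  summary <- data.frame(
    axis = axes,
    variance_fraction = pca$variance_fraction[axes],
    selected_G = vapply(per_axis, function(z) z$gmm$selected_G, integer(1)),
    model = vapply(per_axis, function(z) z$gmm$selected_model, character(1)),
    allometry_r = vapply(per_axis, function(z) z$allometry$r, numeric(1)),
    allometry_p = padj,
    dimorphic = vapply(per_axis, function(z) z$dimorphic, logical(1)),
    row.names = names(per_axis))
  structure(list(axes = per_axis, summary = summary, alpha = alpha,
                 scores = pca$scores[, axes, drop = FALSE]),
            class = "dimorphism_scan")
}

#' @export
print.dimorphism_scan <- function(x, ...) {
  cat("<dimorphism_scan>\n")
  print(x$summary, digits = 3)
  flagged <- rownames(x$summary)[x$summary$dimorphic]
  cat(if (length(flagged))
    paste0("dimorphic, size-independent axes: ",
           paste(flagged, collapse = ", "), "\n")
    else "no dimorphic axis flagged\n")
  invisible(x)
}

#' Cluster consistency between two binary assignments
#'
#' Counts, over the specimens shared by two analyses (e.g. complete femora
#' and distal epiphyses), how many are attributed to the same cluster, after
#' the optimal relabeling: the maximum agreement over the label bijections
#' (cluster names are arbitrary, so a global label swap costs nothing).
#'
#' @param assign_a,assign_b named vectors of cluster labels (at most two
#'   distinct labels each); names identify specimens.
#' @return list with `n_shared`, `n_consistent`, `ids` (shared specimen
#'   ids), `agreement` (fraction).
#' @export
cluster_consistency <- function(assign_a, assign_b) {
  if (is.null(names(assign_a)) || is.null(names(assign_b)))
    stop("assignments must be named by specimen id")
  if (length(unique(assign_a)) > 2L || length(unique(assign_b)) > 2L)
    stop("assignments must be binary labelled")
  ids <- intersect(names(assign_a), names(assign_b))
  if (!length(ids)) stop("no shared specimens between the two assignments")
  a <- as.integer(factor(assign_a[ids]))
  b <- as.integer(factor(assign_b[ids]))
  same <- sum(a == b)
  n_consistent <- max(same, length(ids) - same)  # identity vs swapped labels
  list(n_shared = length(ids), n_consistent = n_consistent, ids = ids,
       agreement = n_consistent / length(ids))
}

#' Repeatability experiment (operator-noise replication)
#'
#' Emulates repeated landmarking: each of exactly 3 base specimens is
#' replicated `n_rep` times with isotropic Gaussian noise of standard
#' deviation `operator_noise` added to every coordinate, the pooled set is
#' superimposed and ordinated, and separation is summarized on the first two
#' PC axes as (minimum between-specimen distance) / (maximum within-specimen
#' distance).  Separation > 1 means every replicate cloud is grouped with
#' its own specimen and isolated from the others, i.e. biological signal
#' exceeds operator error.
#'
#' @param specimens list of exactly 3 `landmark_config` objects.
#' @param n_rep replicates per specimen (default 10).
#' @param operator_noise noise sd in coordinate units (> 0).
#' @param seed RNG seed for the noise draws.
#' @return list with `configs` (3 * n_rep noisy configurations), `gpa`,
#'   `pca`, `separation`, `replicate_of`.
#' @export
repeatability_experiment <- function(specimens, n_rep = 10L, operator_noise,
                                     seed = 1L) {
  if (length(specimens) != 3L)
    stop("repeatability experiment expects exactly 3 base specimens")
  if (operator_noise <= 0) stop("operator_noise must be positive")
  d01 <- procrustes_distance(specimens[[1]], specimens[[2]])
  d02 <- procrustes_distance(specimens[[1]], specimens[[3]])
  d12 <- procrustes_distance(specimens[[2]], specimens[[3]])
  if (min(d01, d02, d12) < 1e-12)
    warning("two base specimens are identical: separation is not identifiable")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  configs <- list(); origin <- integer(0)
  for (s in 1:3) for (r in seq_len(n_rep)) {
    cc <- specimens[[s]]
    cc$points <- cc$points + matrix(stats::rnorm(length(cc$points),
                                                 sd = operator_noise),
                                    ncol = 3)
    cc$specimen_id <- sprintf("%s_rep%02d", specimens[[s]]$specimen_id, r)
    configs[[length(configs) + 1L]] <- cc
    origin <- c(origin, s)
  }
  g <- gpa(configs)
  p <- shape_pca(g)
  sc <- p$scores[, 1:2, drop = FALSE]
  D <- as.matrix(stats::dist(sc))
  samegrp <- outer(origin, origin, `==`)
  diag(D) <- NA
  within_max <- max(D[samegrp], na.rm = TRUE)
  between_min <- min(D[!samegrp], na.rm = TRUE)
  sep <- between_min / within_max
  if (sep <= 1)
    warning("replicate clouds overlap: separation <= 1")
  list(configs = configs, gpa = g, pca = p, separation = sep,
       replicate_of = origin)
}
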