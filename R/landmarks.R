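#' Landmark configuration for one specimen
#'
#' A `landmark_config` holds one specimen's ordered 3D points together with a
#' per-point class (`anatomical`, `curve_semi`, `surface_semi`) and, for
#' semilandmarks, the curve or patch the point belongs to.  Point order is
#' homologous across specimens of the same element type: point `i` is the
#' "same" locus on every bone.
#'
#' @param points numeric matrix, p x 3, finite coordinates (consistent unit,
#'   e.g. mm; units are treated as opaque throughout the package).
#' @param classes character vector of length p with values in
#'   `c("anatomical", "curve_semi", "surface_semi")`.
#' @param specimen_id single string identifying the specimen.
#' @param element one of `"complete_femur"`, `"proximal_femur"`,
#'   `"distal_femur"`, `"complete_tibia"`.
#' @param side `"left"` or `"right"`.
#' @param group per-point grouping key (curve id for curve semilandmarks,
#'   patch id for surface semilandmarks, `NA` for anatomical landmarks).
#'
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(points, classes,
                            specimen_id = "specimen",
                            element = c("complete_femur", "proximal_femur",
                                        "distal_femur", "complete_tibia"),
                            side = c("left", "right"),
                            group = NULL) {
  element <- match.arg(element)
  side <- match.arg(side)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("points must be a p x 3 matrix")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite")
  p <- nrow(points)
  classes <- as.character(classes)
  if (length(classes) != p)
    stop("classes must have one entry per point (", p, "), got ",
         length(classes))
  bad <- setdiff(unique(classes),
                 c("anatomical", "curve_semi", "surface_semi"))
  if (length(bad))
    stop("unknown landmark class: ", paste(bad, collapse = ", "))
  if (is.null(group)) group <- rep(NA_character_, p)
  group <- as.character(group)
  if (length(group) != p)
    stop("group must have one entry per point")
  structure(list(specimen_id = as.character(specimen_id)[1],
                 element = element, side = side,
                 points = points, classes = classes, group = group),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  tab <- table(factor(x$classes,
                      c("anatomical", "curve_semi", "surface_semi")))
  cat(sprintf(
    "<landmark_config> %s  [%s, %s]  %d points (%d anatomical, %d curve, %d surface)\n",
    x$specimen_id, x$element, x$side, nrow(x$points),
    tab[["anatomical"]], tab[["curve_semi"]], tab[["surface_semi"]]))
  invisible(x)
}

#' @export
as.matrix.landmark_config <- function(x, ...) x$points

is_landmark_config <- function(x) inherits(x, "landmark_config")

## Extract the coordinate matrix whether given a config or a bare matrix.
coords_of <- function(x) {
  if (is_landmark_config(x)) x$points else as.matrix(x)
}

## Replace coordinates, keeping metadata.
set_coords <- function(config, points) {
  stopifnot(is_landmark_config(config),
            nrow(points) == nrow(config$points))
  config$points <- as.matrix(points)
  config
}

check_homologous <- function(configs) {
  if (!length(configs)) stop("no configurations supplied")
  if (!all(vapply(configs, is_landmark_config, logical(1))))
    stop("all inputs must be landmark_config objects")
  p <- vapply(configs, function(cc) nrow(cc$points), integer(1))
  if (length(unique(p)) != 1L)
    stop("configurations have differing point counts: ",
         paste(unique(p), collapse = ", "))
  el <- unique(vapply(configs, `[[`, character(1), "element"))
  if (length(el) != 1L)
    stop("mixed element types: ", paste(el, collapse = ", "))
  invisible(p[1])
}

#' Mirror a configuration to left-side form
#'
#' Negates the first (mediolateral) axis so right-side elements can be pooled
#' with left-side ones before superimposition.  The rotation step of
#' Procrustes fitting excludes reflections, so mirroring must happen (if at
#' all) before analysis; whether to mirror is a user toggle.
#'
#' @param config a `landmark_config`.
#' @param axis which coordinate axis to negate (default 1).
#' @return the mirrored configuration, with `side` flipped.
#' @export
mirror_config <- function(config, axis = 1L) {
  stopifnot(is_landmark_config(config))
  config$points[, axis] <- -config$points[, axis]
  config$side <- if (config$side == "left") "right" else "left"
  config
}
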