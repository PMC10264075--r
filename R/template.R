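#' Template definition
#'
#' The reference specimen that drives semilandmark treatment: its landmark
#' configuration, its surface mesh, the ordered index paths of the curve
#' semilandmarks (each anchored at anatomical landmarks at both ends), and
#' the index sets of the surface patches.  All indices are 1-based into the
#' template configuration.
#'
#' @param template_config `landmark_config` of the reference specimen.
#' @param template_mesh optional `bone_mesh` of the reference surface.
#' @param curves named list of integer index paths; each path must start and
#'   end at an anatomical landmark, with curve semilandmarks in between.
#' @param patches named list of integer index sets of surface semilandmarks.
#' @param fragments optional named list of index subsets (e.g. `proximal`,
#'   `distal`) defining fragment extractions.
#' @return object of class `template_definition`.
#' @export
template_definition <- function(template_config, template_mesh = NULL,
                                curves = list(), patches = list(),
                                fragments = list()) {
  stopifnot(is_landmark_config(template_config))
  if (!is.null(template_mesh)) stopifnot(inherits(template_mesh, "bone_mesh"))
  cls <- template_config$classes
  for (nm in names(curves)) {
    path <- curves[[nm]]
    if (length(path) < 3L)
      stop("curve '", nm, "' must have at least one semilandmark between anchors")
    ends <- cls[path[c(1, length(path))]]
    if (!all(ends == "anatomical"))
      stop("curve '", nm, "' must start and end at an anatomical landmark")
    mid <- cls[path[-c(1, length(path))]]
    if (!all(mid == "curve_semi"))
      stop("curve '", nm, "' interior points must be curve semilandmarks")
  }
  for (nm in names(patches)) {
    if (!all(cls[patches[[nm]]] == "surface_semi"))
      stop("patch '", nm, "' must index surface semilandmarks")
  }
  covered <- c(unlist(lapply(curves, function(p) p[-c(1, length(p))])),
               unlist(patches))
  semis <- which(cls != "anatomical")
  if (!setequal(covered, semis))
    stop("every semilandmark must belong to exactly one curve or patch")
  structure(list(template_config = template_config,
                 template_mesh = template_mesh,
                 curves = curves, patches = patches,
                 fragments = fragments),
            class = "template_definition")
}

#' @export
print.template_definition <- function(x, ...) {
  counts <- landmark_census(x)
  cat(sprintf(
    "<template_definition> %d points (%d anatomical, %d curve in %d curves, %d surface in %d patches)%s\n",
    sum(counts), counts[["anatomical"]], counts[["curve_semi"]],
    length(x$curves), counts[["surface_semi"]], length(x$patches),
    if (is.null(x$template_mesh)) "" else ", with mesh"))
  invisible(x)
}

#' Per-class landmark counts of a template or configuration
#'
#' @param x `template_definition` or `landmark_config`.
#' @return named integer vector (anatomical, curve_semi, surface_semi).
#' @export
landmark_census <- function(x) {
  cfg <- template_config_or_null(x)
  table(factor(cfg$classes, c("anatomical", "curve_semi", "surface_semi")))
}

#' Write / read a template descriptor (JSON)
#'
#' Persists the structural metadata of a template — curve index paths, patch
#' index sets, per-point classes and groups, fragment subsets — so that bare
#' coordinate files (e.g. TPS text) can be re-attached to their structure.
#' Coordinates and mesh are stored alongside.
#'
#' @param template a `template_definition`.
#' @param path output JSON file.
#' @return `path` invisibly, or for the reader a `template_definition`.
#' @export
write_template_descriptor <- function(template, path) {
  stopifnot(inherits(template, "template_definition"))
  cfg <- template$template_config
  obj <- list(element = cfg$element, side = cfg$side,
              specimen_id = cfg$specimen_id,
              classes = cfg$classes, group = cfg$group,
              points = unname(as.matrix(cfg$points)),
              curves = template$curves, patches = template$patches,
              fragments = template$fragments)
  if (!is.null(template$template_mesh))
    obj$mesh <- list(vertices = unname(template$template_mesh$vertices),
                     faces = unname(template$template_mesh$faces))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_descriptor
#' @export
read_template_descriptor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- landmark_config(obj$points, obj$classes,
                         specimen_id = obj$specimen_id,
                         element = obj$element, side = obj$side,
                         group = obj$group)
  mesh <- NULL
  if (!is.null(obj$mesh))
    mesh <- bone_mesh(obj$mesh$vertices, obj$mesh$faces)
  template_definition(cfg, mesh,
                      curves = lapply(obj$curves, as.integer),
                      patches = lapply(obj$patches, as.integer),
                      fragments = lapply(obj$fragments, as.integer))
}
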