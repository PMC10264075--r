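## ---- primitive surfaces -------------------------------------------------

golden_angle <- pi * (3 - sqrt(5))

## n points spiralling around a cylinder of radius r between z0 and z1.
cylinder_spiral <- function(n, z0, z1, r, theta0 = 0) {
  k <- seq_len(n)
  z <- if (n == 1) (z0 + z1) / 2 else z0 + (z1 - z0) * (k - 1) / (n - 1)
  th <- theta0 + golden_angle * k
  cbind(r * cos(th), r * sin(th), z)
}

## n near-uniform points on a sphere (Fibonacci lattice).
sphere_fibonacci <- function(n, center, r) {
  k <- seq_len(n)
  zf <- 1 - 2 * (k - 0.5) / n
  rad <- sqrt(pmax(1 - zf^2, 0))
  th <- golden_angle * k
  sweep(r * cbind(rad * cos(th), rad * sin(th), zf), 2, center, `+`)
}

uv_sphere_mesh <- function(center, r, n_theta = 12L, n_phi = 10L) {
  phis <- seq(0, pi, length.out = n_phi + 1L)[-c(1, n_phi + 1L)]
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  V <- rbind(c(0, 0, r),
             do.call(rbind, lapply(phis, function(ph)
               cbind(r * sin(ph) * cos(thetas), r * sin(ph) * sin(thetas),
                     r * cos(ph)))),
             c(0, 0, -r))
  V <- sweep(V, 2, center, `+`)
  nb <- length(phis)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  for (j in seq_len(n_theta)) {                       # top cap
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(nb - 1L)) for (j in seq_len(n_theta)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j)
    d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, cc, b)
    faces[[length(faces) + 1L]] <- c(b, cc, d)
  }
  bottom <- nrow(V)
  for (j in seq_len(n_theta)) {                       # bottom cap
    faces[[length(faces) + 1L]] <- c(bottom, idx(nb, j + 1L), idx(nb, j))
  }
  bone_mesh(V, do.call(rbind, faces))
}

cylinder_mesh <- function(z0, z1, r, n_theta = 24L, n_z = 32L) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(z0, z1, length.out = n_z)
  V <- do.call(rbind, lapply(zs, function(z)
    cbind(r * cos(thetas), r * sin(thetas), z)))
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  for (i in seq_len(n_z - 1L)) for (j in seq_len(n_theta)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, b, cc)
    faces[[length(faces) + 1L]] <- c(b, d, cc)
  }
  bone_mesh(V, do.call(rbind, faces))
}

merge_meshes <- function(...) {
  parts <- list(...)
  V <- NULL; Fc <- NULL; off <- 0L
  for (m in parts) {
    V <- rbind(V, m$vertices)
    Fc <- rbind(Fc, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  bone_mesh(V, Fc)
}

## Largest-remainder apportionment of `total` over non-negative weights,
## with a per-cell minimum.
apportion <- function(total, weights, minimum = 1L) {
  k <- length(weights)
  if (total < k * minimum) stop("count too small to populate all groups")
  raw <- weights / sum(weights) * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  while (any(out < minimum)) {          # steal from the largest group
    out[which.min(out)] <- out[which.min(out)] + 1L
    out[which.max(out)] <- out[which.max(out)] - 1L
  }
  as.integer(out)
}

## ---- the ideal femur ----------------------------------------------------

#' Build the synthetic template femur
#'
#' Constructs a parametric left femur of unit proximodistal length (distal
#' end at z = 0, proximal at z = 1; +x medial, +y anterior): a tubular
#' shaft, an offset femoral head sphere, a greater-trochanter lobe, and two
#' distal condyle lobes; populates it with anatomical landmarks at defined
#' loci (head poles, trochanter points, the proximal point of the fourth
#' trochanter, condyle extrema, the proximal point of the anteromedial
#' flange, mid-shaft points), curve semilandmarks along six anchored ridge
#' curves, and surface semilandmarks in three patch bands (proximal,
#' mid-shaft, distal); builds a triangulated mesh of the same surfaces and
#' snaps the surface semilandmarks onto it; and records the proximal/distal
#' fragment index subsets (the proximal subset reaches distally to the
#' anteromedial-flange anchor, the distal subset proximally to the
#' fourth-trochanter anchor, so the two overlap across the mid-shaft
#' surface band).
#'
#' With the default census of 25 anatomical / 99 curve / 495 surface
#' landmarks the configuration has 619 points and the fragment subsets have
#' 479 points each (11/26/442 proximal, 10/45/424 distal).
#'
#' @param counts named or positional integer vector:
#'   (anatomical, curve, surface) landmark counts.
#' @param with_mesh build the triangle mesh (default TRUE).
#' @param element element label for the configuration.
#' @return a `template_definition` with `fragments$proximal` and
#'   `fragments$distal` index subsets.
#' @export
build_ideal_femur <- function(counts = c(anatomical = 25L, curve = 99L,
                                         surface = 495L),
                              with_mesh = TRUE,
                              element = "complete_femur") {
  na <- as.integer(counts[[1]]); nc <- as.integer(counts[[2]])
  ns <- as.integer(counts[[3]])
  rs <- 0.06                       # shaft radius
  head_c <- c(0.13, 0, 0.90); head_r <- 0.085
  gt_c <- c(-0.075, 0, 0.94); gt_r <- 0.045
  mc_c <- c(0.07, -0.02, 0.06); lc_c <- c(-0.07, -0.02, 0.06)
  cond_r <- 0.065
  z_troch <- 0.78                  # fourth-trochanter proximal point
  z_flange <- 0.30                 # anteromedial-flange proximal point

  ## 25 canonical anatomical loci; droppable ones removed first when
  ## na < 25, extras appended along the shaft when na > 25.
  anat <- rbind(
    head_apex      = head_c + c(head_r, 0, 0),
    head_proximal  = head_c + c(0, 0, head_r),
    head_anterior  = head_c + c(0, head_r, 0),
    head_posterior = head_c + c(0, -head_r, 0),
    neck_base      = c(0.06, 0, 0.88),
    gt_tip         = gt_c + c(0, 0, gt_r),
    gt_lateral     = gt_c + c(-gt_r, 0, 0),
    gt_base        = c(-0.06, 0, 0.90),
    troch4_prox    = c(rs * cos(-pi / 2), rs * sin(-pi / 2), z_troch),
    proxshaft_ant  = c(0, rs, 0.80),
    proxshaft_med  = c(rs, 0, 0.82),
    midshaft_med   = c(rs, 0, 0.55),
    midshaft_lat   = c(-rs, 0, 0.55),
    midshaft_ant   = c(0, rs, 0.50),
    midshaft_post  = c(0, -rs, 0.60),
    flange_prox    = c(rs * cos(pi / 4), rs * sin(pi / 4), z_flange),
    distshaft_ant  = c(0, rs, 0.25),
    mcond_medial   = mc_c + c(cond_r, 0, 0),
    mcond_distal   = mc_c + c(0, 0, -cond_r),
    mcond_post     = mc_c + c(0, -cond_r, 0),
    lcond_lateral  = lc_c + c(-cond_r, 0, 0),
    lcond_distal   = lc_c + c(0, 0, -cond_r),
    lcond_post     = lc_c + c(0, -cond_r, 0),
    intercond      = c(0, -0.05, 0.02),
    patellar       = c(0, 0.045, 0.03))
  droppable <- c("midshaft_post", "midshaft_ant", "midshaft_lat",
                 "midshaft_med", "patellar", "lcond_post", "mcond_post",
                 "distshaft_ant", "gt_base", "gt_lateral",
                 "head_posterior", "head_anterior")
  if (na < nrow(anat) - length(droppable))
    stop("anatomical count too small: need at least ",
         nrow(anat) - length(droppable))
  if (na < nrow(anat)) {
    anat <- anat[setdiff(rownames(anat),
                         droppable[seq_len(nrow(anat) - na)]), , drop = FALSE]
  } else if (na > nrow(anat)) {
    extra <- cylinder_spiral(na - nrow(anat), 0.35, 0.72, rs, theta0 = 1)
    rownames(extra) <- paste0("shaft_extra", seq_len(nrow(extra)))
    anat <- rbind(anat, extra)
  }

  ## curve semilandmark counts over the six anchored ridge curves
  curve_defs <- list(
    head_neck   = list(from = "head_proximal", to = "neck_base"),
    trochanter  = list(from = "gt_tip", to = "proxshaft_ant"),
    linea       = list(from = "troch4_prox", to = "flange_prox"),
    mcond_rim   = list(from = "mcond_medial", to = "mcond_distal"),
    lcond_rim   = list(from = "lcond_lateral", to = "lcond_distal"),
    flange_line = list(from = "flange_prox", to = "intercond"))
  ccounts <- apportion(nc, c(13, 13, 28, 15, 15, 15))
  curve_pts <- list(
    head_neck = {                                # arc over the head sphere
      t <- seq(0.1, 0.9, length.out = ccounts[1])
      ang <- pi / 2 * (1 - t)                    # from proximal pole to neck
      sweep(head_r * cbind(-sin(ang) * 0.2 - (1 - sin(ang)) * 0.8,
                           0 * ang, cos(ang)), 2, head_c, `+`)
    },
    trochanter = {                               # Bezier gt_tip -> shaft
      t <- seq(0, 1, length.out = ccounts[2] + 2L)[2:(ccounts[2] + 1L)]
      p0 <- anat["gt_tip", ]; p2 <- anat["proxshaft_ant", ]
      p1 <- c(-0.09, 0.03, 0.92)
      outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
    },
    linea = {                                    # posterior->anteromedial spiral
      t <- seq(0, 1, length.out = ccounts[3] + 2L)[2:(ccounts[3] + 1L)]
      th <- -pi / 2 + t * (pi / 4 + pi / 2)
      z <- z_troch + t * (z_flange - z_troch)
      cbind(rs * cos(th), rs * sin(th), z)
    },
    mcond_rim = {                                # arc on the medial condyle
      t <- seq(0, 1, length.out = ccounts[4] + 2L)[2:(ccounts[4] + 1L)]
      ang <- t * pi / 2
      sweep(cond_r * cbind(cos(ang), 0 * ang, -sin(ang)), 2, mc_c, `+`)
    },
    lcond_rim = {
      t <- seq(0, 1, length.out = ccounts[5] + 2L)[2:(ccounts[5] + 1L)]
      ang <- t * pi / 2
      sweep(cond_r * cbind(-cos(ang), 0 * ang, -sin(ang)), 2, lc_c, `+`)
    },
    flange_line = {                              # anterior descent to fossa
      t <- seq(0, 1, length.out = ccounts[6] + 2L)[2:(ccounts[6] + 1L)]
      p0 <- anat["flange_prox", ]; p2 <- anat["intercond", ]
      p1 <- c(0.02, 0.07, 0.15)
      outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
    })

  ## surface semilandmark bands: head / proximal shaft / mid shaft /
  ## medial condyle / lateral condyle
  scounts <- apportion(ns, c(40, 31, 371, 27, 26), minimum = 3L)
  surf_pts <- list(
    head = sphere_fibonacci(scounts[1], head_c, head_r),
    proxshaft = cylinder_spiral(scounts[2], z_troch + 0.005, 0.915, rs,
                                theta0 = 0.5),
    midshaft = cylinder_spiral(scounts[3], z_flange + 0.005, z_troch - 0.005,
                               rs, theta0 = 2),
    mcond = sphere_fibonacci(scounts[4], mc_c, cond_r),
    lcond = sphere_fibonacci(scounts[5], lc_c, cond_r))

  ## assemble ordering: anatomical, curves, surfaces
  P <- rbind(anat, do.call(rbind, curve_pts), do.call(rbind, surf_pts))
  classes <- c(rep("anatomical", nrow(anat)),
               rep("curve_semi", sum(ccounts)),
               rep("surface_semi", sum(scounts)))
  group <- c(rep(NA_character_, nrow(anat)),
             rep(names(curve_pts), ccounts),
             rep(names(surf_pts), scounts))
  anat_idx <- stats::setNames(seq_len(nrow(anat)), rownames(anat))
  curve_start <- nrow(anat)
  curves <- list(); off <- curve_start
  for (i in seq_along(curve_pts)) {
    nm <- names(curve_pts)[i]
    inner <- off + seq_len(ccounts[i])
    curves[[nm]] <- c(anat_idx[[curve_defs[[nm]]$from]], inner,
                      anat_idx[[curve_defs[[nm]]$to]])
    off <- off + ccounts[i]
  }
  patches <- list(); poff <- curve_start + sum(ccounts)
  for (i in seq_along(surf_pts)) {
    patches[[names(surf_pts)[i]]] <- poff + seq_len(scounts[i])
    poff <- poff + scounts[i]
  }

  mesh <- NULL
  if (with_mesh) {
    mesh <- merge_meshes(
      cylinder_mesh(0.10, 0.92, rs),
      uv_sphere_mesh(head_c, head_r, 16L, 12L),
      uv_sphere_mesh(gt_c, gt_r, 10L, 8L),
      uv_sphere_mesh(mc_c, cond_r, 12L, 10L),
      uv_sphere_mesh(lc_c, cond_r, 12L, 10L))
    ## snap surface semilandmarks onto the polygonal mesh so that identity
    ## projection round-trips exactly
    sidx <- which(classes == "surface_semi")
    P[sidx, ] <- closest_point_mesh(mesh, P[sidx, , drop = FALSE])$points
  }

  cfg <- landmark_config(unname(P), classes, specimen_id = "template",
                         element = element, side = "left", group = group)
  frag_prox <- c(unname(anat_idx[rownames(anat)[anat[, 3] >= z_troch - 1e-9]]),
                 unlist(lapply(curves[c("head_neck", "trochanter")],
                               function(p) p[-c(1, length(p))]),
                        use.names = FALSE),
                 unlist(patches[c("head", "proxshaft", "midshaft")],
                        use.names = FALSE))
  frag_dist <- c(unname(anat_idx[rownames(anat)[anat[, 3] <= z_flange + 1e-9]]),
                 unlist(lapply(curves[c("mcond_rim", "lcond_rim",
                                        "flange_line")],
                               function(p) p[-c(1, length(p))]),
                        use.names = FALSE),
                 unlist(patches[c("midshaft", "mcond", "lcond")],
                        use.names = FALSE))
  template_definition(cfg, mesh, curves = curves, patches = patches,
                      fragments = list(proximal = sort(frag_prox),
                                       distal = sort(frag_dist)))
}

## ---- morphs and populations --------------------------------------------

## Smooth morph deformation applied to any point set in template frame.
## Morph "A": laterally bowed shaft (quadratic x-offset peaking mid-shaft)
## with a slight ventromedial head inclination; morph "B": distal
## lateromedial widening about the sagittal plane.
apply_morph <- function(X, morph, curvature_effect, width_effect,
                        head_tweak = 0.015) {
  X <- as.matrix(X)
  z <- X[, 3]
  if (morph == "A") {
    bow <- pmax(pmin(z, 1), 0)
    X[, 1] <- X[, 1] - curvature_effect * 4 * bow * (1 - bow)
    head_c <- c(0.13, 0, 0.90)
    d2 <- rowSums(sweep(X, 2, head_c)^2)
    w <- exp(-d2 / (2 * 0.12^2))
    X[, 2] <- X[, 2] - head_tweak * w          # head inclined ventrally
    X[, 1] <- X[, 1] + 0.5 * head_tweak * w    # ... and medially
  } else {
    w <- pmin(pmax((0.20 - z) / 0.20, 0), 1)
    X[, 1] <- X[, 1] * (1 + (width_effect - 1) * w)
  }
  X
}

#' Specification of a synthetic bone population
#'
#' Parameters of the two-morph femur population the generator emulates:
#' morph A has a laterally bowed shaft (and narrow distal end), morph B a
#' straight shaft with a wider distal epiphysis — the two dimorphic
#' features are coupled within morph (set `coupled = FALSE` to draw them
#' independently for ablation).  Size is drawn log-normally, independent of
#' morph when `size_morph_coupling = 0`.
#'
#' @param n number of specimens (>= 2).
#' @param mixing proportion of morph B (default 0.5, a 1:1 ratio).
#' @param curvature_effect mid-shaft lateral bow amplitude of morph A, as a
#'   fraction of bone length (default 0.03).
#' @param width_effect distal lateromedial width multiplier of morph B
#'   (default 1.10; morph A has 1.00).
#' @param noise_sd isotropic per-landmark, per-coordinate noise sd as a
#'   fraction of bone length (default 0.005).
#' @param size_mean,size_sd median scale factor and log-scale sd of the
#'   log-normal centroid-size distribution (defaults 1 and 0.08).
#' @param size_morph_coupling shift of morph B's mean log size in units of
#'   `size_sd` (default 0 = size-independent dimorphism).
#' @param seed RNG seed.
#' @param coupled couple bow and width within morph (default TRUE).
#' @param with_meshes also deform the template mesh per specimen?
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n, mixing = 0.5, curvature_effect = 0.03,
                            width_effect = 1.10, noise_sd = 0.005,
                            size_mean = 1, size_sd = 0.08,
                            size_morph_coupling = 0, seed = 1L,
                            coupled = TRUE, with_meshes = FALSE) {
  if (n < 2) stop("population needs n >= 2")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  if (noise_sd < 0 || size_sd < 0 || size_mean <= 0 || width_effect <= 0)
    stop("scales must be positive")
  structure(list(n = as.integer(n), mixing = mixing,
                 curvature_effect = curvature_effect,
                 width_effect = width_effect, noise_sd = noise_sd,
                 size_mean = size_mean, size_sd = size_sd,
                 size_morph_coupling = size_morph_coupling,
                 seed = as.integer(seed), coupled = coupled,
                 with_meshes = with_meshes),
            class = "population_spec")
}

#' Generate a synthetic bone population
#'
#' Draws `spec$n` specimens from the two-morph model: per specimen a morph
#' is drawn by the mixing proportion, the template is deformed by that
#' morph's features, isotropic landmark noise is added, and the specimen is
#' scaled by a log-normal size factor (decoupled from morph unless
#' `size_morph_coupling != 0`).  Fully reproducible from `spec$seed`; the
#' caller's RNG state is untouched.  The morph/size truth is carried
#' separately from the landmark data and is never read by the analysis
#' pipeline.
#'
#' @param spec a `population_spec`.
#' @param template a `template_definition` (see [build_ideal_femur()]).
#' @return object of class `synthetic_population`: `specimens` (list of
#'   `landmark_config`), `meshes` (list or NULL), `truth` (data frame with
#'   `specimen_id`, `morph`, `size_factor`, `centroid_size`), `spec`,
#'   `template`.
#' @export
generate_population <- function(spec, template) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(template, "template_definition"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  tc <- template$template_config
  ## draw the population-level truth in blocks so the random stream (and
  ## hence each specimen's morph and size) does not depend on the
  ## template's landmark count
  is_b_all <- stats::runif(spec$n) < spec$mixing
  bow_draw <- stats::runif(spec$n) < 0.5       # used in uncoupled mode only
  size_all <- exp(stats::rnorm(spec$n,
                               log(spec$size_mean) +
                                 spec$size_morph_coupling * spec$size_sd *
                                 is_b_all,
                               spec$size_sd))
  specimens <- list(); meshes <- list()
  truth <- data.frame(specimen_id = character(0), morph = character(0),
                      size_factor = numeric(0), centroid_size = numeric(0))
  for (i in seq_len(spec$n)) {
    is_b <- is_b_all[i]
    morph <- if (is_b) "B" else "A"
    if (spec$coupled) {
      bow <- if (morph == "A") spec$curvature_effect else 0
      wid <- if (morph == "B") spec$width_effect else 1
    } else {
      bow <- if (bow_draw[i]) spec$curvature_effect else 0
      wid <- if (is_b) spec$width_effect else 1
    }
    X <- tc$points
    if (bow > 0) X <- apply_morph(X, "A", bow, 1)
    if (wid != 1) X <- apply_morph(X, "B", 0, wid)
    ## renormalize to the template centroid size so that size is carried
    ## exclusively by the drawn size factor (exact decoupling from morph)
    X <- X * (centroid_size(tc$points) / centroid_size(X))
    s <- size_all[i]
    Xn <- X + matrix(stats::rnorm(length(X), sd = spec$noise_sd), ncol = 3)
    Xn <- Xn * s
    id <- sprintf("syn%03d", i)
    cfg <- landmark_config(Xn, tc$classes, specimen_id = id,
                           element = tc$element, side = "left",
                           group = tc$group)
    specimens[[i]] <- cfg
    if (spec$with_meshes) {
      V <- template$template_mesh$vertices
      if (bow > 0) V <- apply_morph(V, "A", bow, 1)
      if (wid != 1) V <- apply_morph(V, "B", 0, wid)
      meshes[[i]] <- bone_mesh(V * s, template$template_mesh$faces)
    }
    truth <- rbind(truth, data.frame(specimen_id = id, morph = morph,
                                     size_factor = s,
                                     centroid_size = centroid_size(cfg)))
  }
  names(specimens) <- truth$specimen_id
  structure(list(specimens = specimens,
                 meshes = if (spec$with_meshes) meshes else NULL,
                 truth = truth, spec = spec, template = template),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> n = %d (%d morph A, %d morph B)\n",
              nrow(x$truth), sum(x$truth$morph == "A"),
              sum(x$truth$morph == "B")))
  invisible(x)
}

#' Extract a fragment (proximal or distal epiphysis) configuration
#'
#' Returns the template-defined index subset of a complete configuration
#' for the requested portion.  The proximal subset is anchored at the
#' fourth-trochanter analogue, the distal subset at the anteromedial-flange
#' analogue; with the default femur census each subset has 479 points
#' (11/26/442 and 10/45/424 anatomical/curve/surface).
#'
#' @param specimen `landmark_config` of a complete bone.
#' @param portion `"proximal"` or `"distal"`.
#' @param template the `template_definition` the specimen follows.
#' @return a `landmark_config` with element `proximal_femur` /
#'   `distal_femur`.
#' @export
extract_fragment <- function(specimen, portion = c("proximal", "distal"),
                             template) {
  portion <- match.arg(portion)
  stopifnot(is_landmark_config(specimen),
            inherits(template, "template_definition"))
  idx <- template$fragments[[portion]]
  if (is.null(idx)) stop("template defines no '", portion, "' fragment")
  landmark_config(specimen$points[idx, , drop = FALSE],
                  specimen$classes[idx],
                  specimen_id = specimen$specimen_id,
                  element = paste0(portion, "_femur"),
                  side = specimen$side,
                  group = specimen$group[idx])
}

#' Fragment template
#'
#' Restriction of a template to one fragment subset: curves fully contained
#' in the subset are kept (indices remapped), surface patches are
#' intersected with the subset.
#'
#' @inheritParams extract_fragment
#' @return a `template_definition` for the fragment.
#' @export
extract_fragment_template <- function(template,
                                      portion = c("proximal", "distal")) {
  portion <- match.arg(portion)
  idx <- template$fragments[[portion]]
  if (is.null(idx)) stop("template defines no '", portion, "' fragment")
  cfg <- extract_fragment(template$template_config, portion, template)
  remap <- match(seq_len(nrow(template$template_config$points)), idx)
  curves <- list()
  for (nm in names(template$curves)) {
    path <- template$curves[[nm]]
    if (all(path %in% idx)) curves[[nm]] <- remap[path]
  }
  patches <- list()
  for (nm in names(template$patches)) {
    sub <- intersect(template$patches[[nm]], idx)
    if (length(sub)) patches[[nm]] <- remap[sub]
  }
  template_definition(cfg, NULL, curves = curves, patches = patches)
}
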