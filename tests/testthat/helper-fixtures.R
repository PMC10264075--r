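# Shared fixtures, built in code at test time.

# Small femur template (fast): 15 anatomical, 30 curve, 120 surface points.
small_femur <- local({
  cache <- NULL
  function(with_mesh = FALSE) {
    key <- if (with_mesh) "mesh" else "plain"
    if (is.null(cache[[key]]))
      cache[[key]] <<- build_ideal_femur(c(15L, 30L, 120L),
                                         with_mesh = with_mesh)
    cache[[key]]
  }
})

# Random landmark configuration with plausible metadata.
random_config <- function(p, seed = 1, id = "rand") {
  set.seed(seed)
  landmark_config(matrix(rnorm(3 * p), p, 3),
                  rep("anatomical", p), specimen_id = id)
}

# Random proper rotation matrix.
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Tiny toy template: two straight-line curves with 3 sliding points in
# total, plus anchors (two of them off-plane so the 3D spline kernel is
# non-singular); used for grid-search sliding checks.
toy_curve_template <- function() {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0),      # anchors curve 1
               c(0, 1, 0.3), c(1, 1, 0.3),  # anchors curve 2
               c(0.35, 0, 0), c(0.62, 0, 0),  # 2 semis on curve 1
               c(0.55, 1, 0.3),               # 1 semi on curve 2
               c(0.5, 0.5, 1), c(0.2, -0.5, -0.8))  # off-plane anchors
  cls <- c(rep("anatomical", 4), rep("curve_semi", 3),
           rep("anatomical", 2))
  cfg <- landmark_config(pts, cls, specimen_id = "toy")
  template_definition(cfg, NULL,
                      curves = list(c1 = c(1, 5, 6, 2), c2 = c(3, 7, 4)),
                      patches = list())
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
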