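test_that("sliding at a stationary point does not move, and anchors never move", {
  tpl <- toy_curve_template()
  cfg <- tpl$template_config
  # reference == config: already at the bending-energy minimum (energy 0)
  out <- slide_iteration(cfg, cfg, tpl)
  expect_lt(max(abs(out$points - cfg$points)), 1e-8)

  # a perturbed specimen: anatomical anchors are bitwise unchanged
  set.seed(2)
  spec <- cfg
  spec$points <- spec$points +
    matrix(rnorm(length(spec$points), sd = 0.05), ncol = 3)
  ref <- cfg
  out2 <- slide_iteration(spec, ref, tpl)
  anat <- which(cfg$classes == "anatomical")
  expect_identical(out2$points[anat, ], spec$points[anat, ])
  # semilandmarks moved somewhere
  expect_gt(max(abs(out2$points - spec$points)), 0)
})

test_that("one slide matches a dense grid search over tangent offsets", {
  tpl <- toy_curve_template()
  ref <- tpl$template_config
  set.seed(5)
  spec <- ref
  # perturb only the 3 sliding points along their own curves
  spec$points[5, 1] <- spec$points[5, 1] + 0.12
  spec$points[6, 1] <- spec$points[6, 1] - 0.09
  spec$points[7, 1] <- spec$points[7, 1] + 0.15
  E <- bending_energy_matrix(ref$points)

  out <- slide_iteration(spec, ref, tpl, E = E)
  be_impl <- attr(out, "bending_energy")

  # oracle: exhaustive grid over the three tangential offsets.
  # curves are straight lines along +x, so tangent displacement = x shift
  # and polyline re-projection is the identity for in-segment moves.
  offs <- seq(-0.5, 0.5, by = 0.01)
  be_grid <- Inf
  Y <- spec$points
  for (t1 in offs) {
    Y1 <- Y; Y1[5, 1] <- Y[5, 1] + t1
    for (t2 in offs) {
      Y2 <- Y1; Y2[6, 1] <- Y[6, 1] + t2
      # offsets move only x of point 7: the objective restricted to the
      # grid line is evaluated at every t3 at once
      base <- sum(Y2 * (E %*% Y2))
      be_t3 <- base + 2 * offs * sum(E[7, ] * Y2[, 1]) + offs^2 * E[7, 7]
      m <- min(be_t3)
      if (m < be_grid) be_grid <- m
    }
  }
  expect_lte(be_impl, be_grid + 1e-10)
  expect_equal(be_impl, be_grid, tolerance = 1e-3)
})

test_that("relaxation traces are non-increasing and fixed points are stable", {
  tpl <- small_femur()
  set.seed(6)
  ps <- population_spec(n = 6, seed = 11)
  pop <- generate_population(ps, tpl)

  r0 <- relax_to_template(pop$specimens, tpl, n_iter = 0)
  expect_identical(r0$configs[[1]]$points, pop$specimens[[1]]$points)

  r5 <- relax_to_template(pop$specimens, tpl, n_iter = 5)
  expect_true(all(diff(r5$bending_energy_trace) <= 1e-9))
  anat <- which(tpl$template_config$classes == "anatomical")
  for (i in seq_along(pop$specimens))
    expect_identical(r5$configs[[i]]$points[anat, ],
                     pop$specimens[[i]]$points[anat, ])

  # a specimen equal to the template stays put through template relaxation
  rt <- relax_to_template(list(tpl$template_config), tpl, n_iter = 3)
  expect_lt(max(abs(rt$configs[[1]]$points - tpl$template_config$points)),
            1e-8)

  r2 <- relax_to_consensus(r5$configs, tpl, n_iter = 2)
  expect_true(all(diff(r2$bending_energy_trace) <= 1e-9))
  expect_error(relax_to_template(pop$specimens, tpl, n_iter = -1),
               "non-negative")
})

test_that("consensus relaxation is permutation invariant and fixed on
           identical configurations", {
  tpl <- small_femur()
  ps <- population_spec(n = 5, seed = 21)
  pop <- generate_population(ps, tpl)
  r <- relax_to_consensus(pop$specimens, tpl, n_iter = 1)
  perm <- c(3, 1, 5, 2, 4)
  rp <- relax_to_consensus(pop$specimens[perm], tpl, n_iter = 1)
  for (k in 1:5)
    expect_lt(max(abs(r$configs[[perm[k]]]$points - rp$configs[[k]]$points)),
              1e-9)

  same <- lapply(1:4, function(i) tpl$template_config)
  rs <- relax_to_consensus(same, tpl, n_iter = 2)
  # identical configs: consensus is their shape; sliding finds zero offsets
  expect_lt(max(abs(rs$configs[[1]]$points - tpl$template_config$points)),
            1e-6)
})

test_that("curve semilandmarks stay on their polyline during sliding", {
  tpl <- small_femur()
  ps <- population_spec(n = 3, seed = 31)
  pop <- generate_population(ps, tpl)
  spec <- pop$specimens[[1]]
  out <- slide_iteration(spec, tpl$template_config, tpl)
  # every slid curve point lies on the original polyline of its curve
  for (path in tpl$curves) {
    inner <- path[-c(1, length(path))]
    poly <- spec$points[path, , drop = FALSE]
    reproj <- osteomorph:::project_polyline(out$points[inner, , drop = FALSE],
                                            poly)
    expect_lt(max(abs(out$points[inner, ] - reproj)), 1e-9)
  }
})

test_that("patch projection transfers surface points and is affine equivariant", {
  tpl <- small_femur(with_mesh = TRUE)
  tc <- tpl$template_config
  fixed_idx <- which(tc$classes != "surface_semi")
  surf_idx <- which(tc$classes == "surface_semi")
  fixed <- landmark_config(tc$points[fixed_idx, ], tc$classes[fixed_idx],
                           specimen_id = "self", group = tc$group[fixed_idx])

  # identity: projected surface points equal the template's
  proj <- project_patch(tpl, tpl$template_mesh, fixed)
  expect_lt(max(abs(proj$points[surf_idx, ] - tc$points[surf_idx, ])), 1e-6)

  # affine specimen: projection lands on the affine image of the template
  A <- diag(c(1.3, 0.8, 1.1)) %*% random_rotation(4)
  b <- c(2, -1, 0.5)
  aff <- function(X) X %*% A + matrix(b, nrow(X), 3, byrow = TRUE)
  mesh_a <- bone_mesh(aff(tpl$template_mesh$vertices),
                      tpl$template_mesh$faces)
  fixed_a <- landmark_config(aff(tc$points[fixed_idx, ]),
                             tc$classes[fixed_idx], specimen_id = "aff",
                             group = tc$group[fixed_idx])
  proj_a <- project_patch(tpl, mesh_a, fixed_a)
  expect_lt(max(abs(proj_a$points[surf_idx, ] - aff(tc$points[surf_idx, ]))),
            1e-4)
  expect_error(project_patch(tpl, bone_mesh(matrix(0, 0, 3),
                                            matrix(integer(0), 0, 3)),
                             fixed), "empty mesh")
})

test_that("closest-point projection returns on-surface points unchanged", {
  tpl <- small_femur(with_mesh = TRUE)
  mesh <- tpl$template_mesh
  # barycenters of a few faces are on the surface already
  fc <- mesh$faces[c(1, 5, 20), ]
  bary <- t(apply(fc, 1, function(f) colMeans(mesh$vertices[f, ])))
  cp <- closest_point_mesh(mesh, bary)
  expect_lt(max(abs(cp$points - bary)), 1e-10)
  expect_lt(max(cp$distance), 1e-10)
})
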