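test_that("consensus mesh warping is exact for identity and affine targets", {
  tpl <- small_femur(with_mesh = TRUE)
  tc <- tpl$template_config

  # consensus equal to the template: mesh unchanged
  fake_gpa <- structure(list(consensus = tc$points), class = "gpa_result")
  m <- consensus_mesh(tpl, fake_gpa)
  expect_lt(max(abs(m$vertices - tpl$template_mesh$vertices)), 1e-6)

  # affine consensus: mesh affinely transformed
  A <- diag(c(0.9, 1.2, 1.05)); b <- c(1, 2, 3)
  fake_aff <- structure(list(consensus = tc$points %*% A +
                               matrix(b, nrow(tc$points), 3, byrow = TRUE)),
                        class = "gpa_result")
  ma <- consensus_mesh(tpl, fake_aff)
  expect_lt(max(abs(ma$vertices - (tpl$template_mesh$vertices %*% A +
                                     matrix(b, nrow(tpl$template_mesh$vertices),
                                            3, byrow = TRUE)))), 1e-6)

  # landmarks embedded in the warped mesh coincide with the target
  set.seed(16)
  target <- tc$points + matrix(rnorm(length(tc$points), sd = 0.01), ncol = 3)
  fake2 <- structure(list(consensus = target), class = "gpa_result")
  model <- tps_fit(tc$points, target)
  expect_lt(max(abs(tps_warp(model, tc$points) - target)), 1e-6)
})

test_that("cluster mean shapes are linear in the scores and symmetric", {
  set.seed(18)
  tpl <- small_femur()
  tc <- tpl$template_config
  dir1 <- matrix(rnorm(length(tc$points)), ncol = 3)
  dir1 <- dir1 / sqrt(sum(dir1^2))
  morph <- rep(c(-1, 1), each = 10)
  cfgs <- lapply(1:20, function(i)
    landmark_config(tc$points + morph[i] * 0.05 * dir1 +
                      matrix(rnorm(length(tc$points), sd = 0.002), ncol = 3),
                    tc$classes, specimen_id = sprintf("s%02d", i),
                    group = tc$group))
  g <- gpa(cfgs)
  p <- shape_pca(g)
  gm <- fit_gmm_1d(p$scores[, 1])
  expect_equal(gm$selected_G, 2L)
  cs <- cluster_mean_shapes(p, gm, axis = 1)
  expect_length(cs$clusters, 2)
  expect_equal(nrow(cs$clusters[[1]]$shape), nrow(tc$points))
  # symmetry about the consensus for balanced +/- scores
  d1 <- cs$clusters[[1]]$shape - cs$consensus
  d2 <- cs$clusters[[2]]$shape - cs$consensus
  expect_equal(d1, -d2, tolerance = 1e-2)
  # linearity: doubling the mean score doubles the offset
  s1 <- cs$clusters[[1]]$mean_score
  flat1 <- p$mean_flat + s1 * p$loadings[, 1]
  flat2 <- p$mean_flat + 2 * s1 * p$loadings[, 1]
  off1 <- matrix(flat1, ncol = 3, byrow = TRUE) - cs$consensus
  off2 <- matrix(flat2, ncol = 3, byrow = TRUE) - cs$consensus
  expect_equal(off2, 2 * off1, tolerance = 1e-10)

  # degenerate: G=1 mixtures cannot give cluster shapes
  gm1 <- suppressWarnings(fit_gmm_1d(rnorm(20)))
  if (gm1$selected_G < 2) expect_error(cluster_mean_shapes(p, gm1), "at least 2")

  # export produces CSV per cluster
  dir <- withr::local_tempdir()
  paths <- export_cluster_shapes(cs, dir)
  expect_true(all(file.exists(file.path(dir, c("cluster1_landmarks.csv",
                                               "cluster2_landmarks.csv")))))
})
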