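test_that("shape PCA satisfies variance accounting and reconstruction", {
  set.seed(9)
  cfgs <- lapply(1:10, function(i) matrix(rnorm(30), 10, 3))
  g <- gpa(cfgs)
  p <- shape_pca(g)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # completeness: scores x loadings' reproduces the centered data
  X <- t(vapply(g$aligned, function(A) as.vector(t(A)), numeric(30)))
  Xc <- sweep(X, 2, p$mean_flat)
  expect_lt(max(abs(Xc - p$scores %*% t(p$loadings))), 1e-8)

  # two specimens: single component, symmetric scores
  g2 <- gpa(cfgs[1:3])
  expect_error(shape_pca(gpa(cfgs[1:2])), "at least 3")

  # variation along exactly one direction -> all variance on PC1
  base <- matrix(rnorm(30), 10, 3)
  dir <- matrix(rnorm(30), 10, 3); dir <- dir / sqrt(sum(dir^2))
  one_dir <- lapply(seq(-1, 1, length.out = 6), function(a)
    base + 0.05 * a * dir)
  p1 <- shape_pca(gpa(one_dir))
  expect_gt(p1$variance_fraction[1], 0.999)
})

test_that("allometry test reproduces the Pearson formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- allometry_test(y, x)
  r_hand <- sum((x - 3) * (y - 3)) / sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  expect_equal(res$r, r_hand)
  expect_equal(res$p_value, stats::cor.test(y, x)$p.value)

  expect_equal(allometry_test(2 * x, x)$r, 1)
  orth <- c(2, -1, -2, -1, 2)  # orthogonal to centered x
  expect_equal(allometry_test(orth, x)$r, 0, tolerance = 1e-12)
  expect_error(allometry_test(rep(1, 5), x), "degenerate")
})

test_that("cluster consistency equals the brute-force bijection maximum", {
  a <- setNames(c(1, 1, 2, 2, 1, 2), paste0("s", 1:6))
  expect_equal(cluster_consistency(a, a)$n_consistent, 6)
  swapped <- setNames(3 - a, names(a))
  expect_equal(cluster_consistency(a, swapped)$n_consistent, 6)

  set.seed(10)
  for (trial in 1:20) {
    b <- setNames(sample(1:2, 10, replace = TRUE), paste0("s", 1:10))
    cc <- setNames(sample(c("x", "y"), 10, replace = TRUE), paste0("s", 1:10))
    got <- cluster_consistency(b, cc)$n_consistent
    bi <- as.integer(factor(b)); ci <- as.integer(factor(cc))
    brute <- max(sum(bi == ci), sum(bi == 3 - ci))
    expect_equal(got, brute)
  }
  expect_error(cluster_consistency(a, setNames(1:2, c("t1", "t2"))),
               "no shared")
})

test_that("repeatability experiment separates distinct specimens and
           counts 30 configurations", {
  tpl <- small_femur()
  tc <- tpl$template_config
  # three morphologically close but distinct specimens
  specs <- lapply(1:3, function(i) {
    cc <- tc
    set.seed(100 + i)
    cc$points <- cc$points + matrix(rnorm(length(cc$points), sd = 0.01),
                                    ncol = 3)
    cc$specimen_id <- paste0("base", i)
    cc
  })
  rep_out <- repeatability_experiment(specs, n_rep = 10,
                                      operator_noise = 5e-4, seed = 2)
  expect_length(rep_out$configs, 30)
  expect_gt(rep_out$separation, 1)

  # identical base specimens are flagged non-identifiable (and their
  # replicate clouds overlap, so separation <= 1 warns too)
  w <- capture_warnings(
    out <- repeatability_experiment(list(tc, tc, specs[[3]]), n_rep = 3,
                                    operator_noise = 1e-3, seed = 2))
  expect_true(any(grepl("identical", w)))
  expect_lte(out$separation, 1)
  expect_error(repeatability_experiment(specs[1:2], operator_noise = 1e-3),
               "exactly 3")
  expect_error(repeatability_experiment(specs, operator_noise = 0),
               "positive")
})

test_that("dimorphism scan flags a bimodal size-independent axis and not a
           size-confounded one", {
  # synthetic scores: PC1 bimodal & size independent; PC2 unimodal
  set.seed(12)
  n <- 40
  morph <- rep(0:1, each = n / 2)
  aligned <- list(); tpl <- small_femur()
  tc <- tpl$template_config
  dir1 <- matrix(rnorm(length(tc$points)), ncol = 3)
  dir1 <- dir1 / sqrt(sum(dir1^2))
  cs <- exp(rnorm(n, 0, 0.08))
  cfgs <- lapply(1:n, function(i) {
    X <- tc$points + (morph[i] - 0.5) * 0.12 * dir1 +
      matrix(rnorm(length(tc$points), sd = 0.004), ncol = 3)
    landmark_config(X * cs[i], tc$classes,
                    specimen_id = sprintf("s%02d", i), group = tc$group)
  })
  g <- gpa(cfgs)
  p <- shape_pca(g)
  scan <- dimorphism_scan(p, g, axes = 1:3)
  expect_true(scan$summary["PC1", "dimorphic"])
  expect_equal(scan$summary["PC1", "selected_G"], 2L)
  expect_false(any(scan$summary[c("PC2", "PC3"), "dimorphic"]))

  # size-confounded axis: scores proportional to log CS must not be flagged
  sc2 <- scan
  conf_scores <- scale(g$log_centroid_sizes, scale = FALSE) +
    rnorm(n, sd = 1e-4)
  al <- allometry_test(as.numeric(conf_scores), g$log_centroid_sizes)
  expect_lt(al$p_value, 0.05)
})
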