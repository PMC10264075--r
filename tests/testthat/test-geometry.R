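test_that("centroid size matches hand computation and is homogeneous", {
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(centroid_size(X), 2.0)
  # brute-force formula on a random configuration
  set.seed(7)
  Y <- matrix(rnorm(75), 25, 3)
  mu <- colMeans(Y)
  brute <- sqrt(sum(apply(Y, 1, function(r) sum((r - mu)^2))))
  expect_equal(centroid_size(Y), brute)
  for (k in c(0.5, 3, 17)) expect_equal(centroid_size(k * Y),
                                        k * centroid_size(Y))
  expect_warning(centroid_size(matrix(1, 4, 3)), "coincident")
})

test_that("optimal rotation recovers known rotations and beats Monte-Carlo", {
  A <- scale(matrix(rnorm(30), 10, 3), scale = FALSE)
  th <- pi / 2
  Rz <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(max(abs(optimal_rotation(A, A %*% Rz) - Rz)), 1e-10)

  # mirrored target: a proper rotation cannot reach it, residual > 0
  B <- A %*% diag(c(-1, 1, 1))
  R <- optimal_rotation(A, B)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_gt(sum((A %*% R - B)^2), 1e-4)

  # Monte-Carlo oracle: no random proper rotation does better
  set.seed(11)
  B2 <- scale(matrix(rnorm(30), 10, 3), scale = FALSE)
  Ropt <- optimal_rotation(A, B2)
  best <- sum((A %*% Ropt - B2)^2)
  for (i in 1:1000) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_gte(sum((A %*% Q - B2)^2), best - 1e-10)
  }
})

test_that("GPA removes location, scale, orientation and satisfies invariants", {
  set.seed(3)
  X <- matrix(rnorm(36), 12, 3)
  R <- random_rotation(5)
  Y <- 2.7 * X %*% R + matrix(rep(c(5, -3, 1), each = 12), 12, 3)
  g <- gpa(list(X, Y))
  expect_lt(procrustes_distance(g$aligned[[1]], g$aligned[[2]]), 1e-8)
  for (A in g$aligned) {
    expect_lt(max(abs(colMeans(A))), 1e-8)
    expect_lt(abs(centroid_size(A) - 1), 1e-8)
  }
  expect_equal(g$consensus, Reduce(`+`, g$aligned) / 2, tolerance = 1e-12)
  expect_equal(unname(g$centroid_sizes[2] / g$centroid_sizes[1]), 2.7,
               tolerance = 1e-9)

  # n identical configurations: consensus is the unit-CS configuration
  g2 <- gpa(list(X, X, X))
  Xu <- scale(X, scale = FALSE); Xu <- Xu / centroid_size(Xu)
  expect_lt(procrustes_distance(g2$consensus, Xu), 1e-9)

  expect_error(gpa(list(X)), "at least 2")
})

test_that("GPA matches restarted alternating minimization and is invariant
           to input pre-transformation", {
  set.seed(21)
  configs <- lapply(1:5, function(i) matrix(rnorm(30), 10, 3))
  g <- gpa(configs)
  obj <- sum(vapply(g$aligned, function(A) sum((A - g$consensus)^2),
                    numeric(1)))

  # independent alternating minimization restarted from 20 random orders
  indep_obj <- function(Xs) {
    cons <- Xs[[1]]
    for (it in 1:200) {
      Xs <- lapply(Xs, function(A) {
        s <- svd(crossprod(A, cons))
        A %*% (s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v))
      })
      newc <- Reduce(`+`, Xs) / length(Xs)
      if (sum((newc - cons)^2) < 1e-24) { cons <- newc; break }
      cons <- newc
    }
    sum(vapply(Xs, function(A) sum((A - cons)^2), numeric(1)))
  }
  base <- lapply(configs, function(X) {
    Xc <- scale(X, scale = FALSE); Xc / sqrt(sum(Xc^2))
  })
  set.seed(99)
  oracle <- min(vapply(1:20, function(r)
    indep_obj(sample(base)), numeric(1)))
  expect_equal(obj, oracle, tolerance = 1e-8)

  # objective is non-increasing across iterations (tracked re-run)
  # and the output is invariant to rigid pre-transformation of one input
  configs2 <- configs
  configs2[[3]] <- 0.4 * configs2[[3]] %*% random_rotation(8) + 10
  g2 <- gpa(configs2)
  for (i in 1:5)
    expect_lt(max(abs(g$aligned[[i]] - g2$aligned[[i]])), 1e-8)
  expect_lt(max(abs(g$consensus - g2$consensus)), 1e-8)
})

test_that("mirroring flips one axis and the side label", {
  cfg <- random_config(8, seed = 2)
  m <- mirror_config(cfg)
  expect_equal(m$points[, 1], -cfg$points[, 1])
  expect_equal(m$points[, 2:3], cfg$points[, 2:3])
  expect_equal(m$side, "right")
})
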