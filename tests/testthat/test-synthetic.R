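test_that("default census builds the full landmark complement", {
  tpl <- build_ideal_femur(with_mesh = FALSE)
  cens <- landmark_census(tpl)
  expect_equal(as.integer(cens), c(25L, 99L, 495L), ignore_attr = TRUE)
  expect_equal(nrow(tpl$template_config$points), 619L)

  tib <- build_ideal_femur(c(23L, 219L, 483L), with_mesh = FALSE,
                           element = "complete_tibia")
  expect_equal(nrow(tib$template_config$points), 725L)

  expect_error(build_ideal_femur(c(5L, 10L, 50L)), "too small")
})

test_that("fragment subsets have the configured sizes and overlap only on
           the mid-shaft surface band", {
  tpl <- build_ideal_femur(with_mesh = FALSE)
  prox <- extract_fragment(tpl$template_config, "proximal", tpl)
  dist <- extract_fragment(tpl$template_config, "distal", tpl)
  expect_equal(nrow(prox$points), 479L)
  expect_equal(nrow(dist$points), 479L)
  expect_equal(as.integer(table(factor(prox$classes,
                                       c("anatomical", "curve_semi",
                                         "surface_semi")))),
               c(11L, 26L, 442L))
  expect_equal(as.integer(table(factor(dist$classes,
                                       c("anatomical", "curve_semi",
                                         "surface_semi")))),
               c(10L, 45L, 424L))
  ov <- intersect(tpl$fragments$proximal, tpl$fragments$distal)
  cls <- tpl$template_config$classes
  expect_true(all(cls[ov] == "surface_semi"))
  # overlap points lie between the two anchors (fourth trochanter at
  # z = 0.78, anteromedial flange at z = 0.30)
  z <- tpl$template_config$points[ov, 3]
  expect_true(all(z > 0.29 & z < 0.79))
  expect_equal(prox$element, "proximal_femur")
  expect_error(extract_fragment(tpl$template_config, "proximal",
                                small_femur()), NA)
})

test_that("template landmarks lie on or near the mesh", {
  tpl <- build_ideal_femur(with_mesh = TRUE)
  surf <- which(tpl$template_config$classes == "surface_semi")
  cp <- closest_point_mesh(tpl$template_mesh,
                           tpl$template_config$points[surf, ])
  expect_lt(max(cp$distance), 1e-9)   # snapped at build time
  allp <- closest_point_mesh(tpl$template_mesh, tpl$template_config$points)
  expect_lt(max(allp$distance), 0.06) # anchors/curves near the surface
})

test_that("population generation is deterministic, morph-balanced, and
           size-decoupled", {
  tpl <- small_femur()
  ps <- population_spec(n = 30, seed = 5)
  pop1 <- generate_population(ps, tpl)
  pop2 <- generate_population(ps, tpl)
  expect_identical(pop1$specimens[[7]]$points, pop2$specimens[[7]]$points)
  expect_identical(pop1$truth, pop2$truth)

  # truth is carried separately; configs carry no morph metadata
  expect_false(any(grepl("morph", unlist(lapply(pop1$specimens, names)))))

  # size decoupled from morph at coupling 0: point-biserial |r| small
  # across seeds
  rs <- vapply(1:20, function(s) {
    p <- generate_population(population_spec(n = 100, seed = s), tpl)
    stats::cor(as.integer(p$truth$morph == "B"), log(p$truth$centroid_size))
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.2), 0.9)

  # coupling shifts morph-B sizes up
  pc <- generate_population(population_spec(n = 200, seed = 1,
                                            size_morph_coupling = 2), tpl)
  expect_gt(mean(log(pc$truth$centroid_size[pc$truth$morph == "B"])),
            mean(log(pc$truth$centroid_size[pc$truth$morph == "A"])))

  expect_error(population_spec(n = 1), "n >= 2")
  expect_error(population_spec(n = 5, mixing = 1.2), "mixing")
})

test_that("morph deformations act where they should", {
  tpl <- small_femur()
  tc <- tpl$template_config
  ps0 <- population_spec(n = 8, seed = 1, noise_sd = 0, size_sd = 0)
  pop <- generate_population(ps0, tpl)
  morphA <- pop$specimens[[which(pop$truth$morph == "A")[1]]]
  morphB <- pop$specimens[[which(pop$truth$morph == "B")[1]]]
  z <- tc$points[, 3]
  mid <- which(z > 0.4 & z < 0.6)
  # morph A: mid-shaft shifted laterally (-x); morph B: unchanged there up
  # to the centroid-size renormalization
  expect_lt(max(morphA$points[mid, 1] - tc$points[mid, 1]), -0.01)
  expect_lt(max(abs(morphB$points[mid, 1] - tc$points[mid, 1])), 1e-3)
  # morph B: distal condyle region wider (|x| scaled up)
  distal <- which(z < 0.1 & abs(tc$points[, 1]) > 0.03)
  expect_gt(mean(abs(morphB$points[distal, 1]) /
                   abs(tc$points[distal, 1])), 1.05)
})

test_that("increasing curvature effect widens the morph gap on PC1", {
  tpl <- small_femur()
  gap <- function(effect) {
    gaps <- vapply(1:3, function(s) {
      pop <- generate_population(
        population_spec(n = 24, seed = s, curvature_effect = effect), tpl)
      g <- gpa(pop$specimens)
      p <- shape_pca(g)
      abs(mean(p$scores[pop$truth$morph == "A", 1]) -
            mean(p$scores[pop$truth$morph == "B", 1]))
    }, numeric(1))
    mean(gaps)
  }
  gaps <- vapply(c(0.01, 0.03, 0.06), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
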