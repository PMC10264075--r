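test_that("MNI reproduces the published femur and tibia counts", {
  inv <- angeac_inventory()
  expect_equal(compute_mni(inv, "femur"), 46L)
  expect_equal(compute_mni(inv, "tibia"), 61L)
  expect_error(compute_mni(inv, "humerus"), "unknown element")

  zero <- element_inventory(data.frame(element = "femur", side = "left",
                                       portion = "complete", mne = 0))
  expect_equal(compute_mni(zero, "femur"), 0L)
})

test_that("MNI equals a brute-force enumeration over side x portion", {
  set.seed(15)
  for (trial in 1:25) {
    df <- expand.grid(element = "femur", side = c("left", "right"),
                      portion = c("proximal", "distal", "complete"),
                      stringsAsFactors = FALSE)
    df$mne <- sample(0:40, 6, replace = TRUE)
    inv <- element_inventory(df)
    get <- function(s, p) df$mne[df$side == s & df$portion == p]
    brute <- max(vapply(c("left", "right"), function(s)
      max(get(s, "proximal") + get(s, "complete"),
          get(s, "distal") + get(s, "complete")), numeric(1)))
    expect_equal(compute_mni(inv, "femur"), as.integer(brute))
  }
})

test_that("staged filters reproduce the published sample accounting", {
  inv <- angeac_inventory()
  first_pass <- list(
    stage = "too fragmented or altered",
    counts = data.frame(
      element = c("femur", "femur", "femur", "tibia", "tibia", "tibia"),
      portion = rep(c("complete", "proximal", "distal"), 2),
      n = c(6, 37, 19, 4, 36, 56)))
  distorted <- list(
    stage = "distorted after digitization",
    counts = data.frame(
      element = c("femur", "femur", "femur", "tibia"),
      portion = c("complete", "proximal", "distal", "complete"),
      n = c(3, 14, 8, 4)))

  out1 <- apply_filters(inv, list(first_pass))
  expect_equal(out1$total_removed, 158L)
  expect_equal(out1$total_remaining, 152L)
  digitized <- out1$final
  expect_equal(digitized$n[digitized$element == "femur" &
                             digitized$portion == "complete"], 13)
  expect_equal(digitized$n[digitized$element == "femur" &
                             digitized$portion == "proximal"], 29)
  expect_equal(digitized$n[digitized$element == "femur" &
                             digitized$portion == "distal"], 21)
  expect_equal(digitized$n[digitized$element == "tibia" &
                             digitized$portion == "complete"], 21)

  out2 <- apply_filters(inv, list(first_pass, distorted))
  fin <- out2$final
  expect_equal(fin$n[fin$element == "femur" & fin$portion == "complete"], 10)
  expect_equal(fin$n[fin$element == "femur" & fin$portion == "proximal"], 15)
  expect_equal(fin$n[fin$element == "femur" & fin$portion == "distal"], 13)
  expect_equal(fin$n[fin$element == "tibia" & fin$portion == "complete"], 17)

  # empty ledger leaves the table untouched
  out0 <- apply_filters(inv, list())
  expect_equal(out0$total_remaining, 310L)

  # order sensitivity of stages, invariance of totals
  outr <- apply_filters(inv, list(distorted, first_pass))
  expect_equal(outr$total_remaining, out2$total_remaining)

  over <- list(stage = "impossible", counts = data.frame(
    element = "femur", portion = "complete", n = 100))
  expect_error(apply_filters(inv, list(over)), "impossible")
})
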