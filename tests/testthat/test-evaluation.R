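test_that("Dice handles the canonical cases and is symmetric", {
  aff <- diag(4)
  mk <- function(idx) {
    occ <- array(FALSE, c(4, 4, 4)); occ[idx] <- TRUE
    voxel_mask(occ, aff)
  }
  a <- mk(1:4); b <- mk(3:6)
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(mk(1:4), mk(5:8)), 0)
  expect_equal(dice_score(a, b), 0.5)  # 2*2/(4+4)
  expect_equal(dice_score(a, b), dice_score(b, a))
  expect_error(dice_score(mk(integer(0)), mk(integer(0))), "empty")
  small <- voxel_mask(array(FALSE, c(2, 2, 2)), aff)
  expect_error(dice_score(a, small), "grid")
})

test_that("mask volume scales with the voxel volume and adds over disjoint masks", {
  aff5 <- diag(c(0.5, 0.5, 0.5, 1))
  occ <- array(FALSE, c(10, 10, 10)); occ[1:100] <- TRUE
  expect_equal(mask_volume(voxel_mask(occ, aff5)), 12.5)
  expect_equal(mask_volume(voxel_mask(array(FALSE, c(5, 5, 5)), aff5)), 0)
  aniso <- diag(c(1, 1, 2, 1))
  occ2 <- array(FALSE, c(5, 5, 5)); occ2[1:10] <- TRUE
  expect_equal(mask_volume(voxel_mask(occ2, aniso)), 20)

  a <- array(FALSE, c(6, 6, 6)); a[1:20] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[30:40] <- TRUE
  expect_equal(mask_volume(voxel_mask(a | b, diag(4))),
               mask_volume(voxel_mask(a, diag(4))) +
                 mask_volume(voxel_mask(b, diag(4))))
})

test_that("normalized modal intensity divides by WM mean only in relative mode", {
  aff <- diag(4)
  vol <- array(1.2, c(8, 8, 8))
  struct <- array(FALSE, c(8, 8, 8)); struct[2:4, 2:4, 2:4] <- TRUE
  vol[struct] <- 0.6
  wm <- array(FALSE, c(8, 8, 8)); wm[6:8, 6:8, 6:8] <- TRUE
  sm <- voxel_mask(struct, aff); wmm <- voxel_mask(wm, aff)
  expect_equal(normalized_modal_intensity(vol, sm, wmm, "relative"), 0.5)
  expect_equal(normalized_modal_intensity(vol, sm, NULL, "absolute"), 0.6)
  empty <- voxel_mask(array(FALSE, c(8, 8, 8)), aff)
  expect_error(normalized_modal_intensity(vol, sm, empty, "relative"),
               "white-matter")
})

test_that("intersection-then-erode produces a conservative rater mask", {
  occ1 <- array(FALSE, c(12, 12, 12)); occ1[2:10, 2:10, 2:10] <- TRUE
  occ2 <- array(FALSE, c(12, 12, 12)); occ2[3:11, 3:11, 3:11] <- TRUE
  m <- intersection_eroded_mask(voxel_mask(occ1, diag(4)),
                                voxel_mask(occ2, diag(4)))
  # intersection is 3:10 cubed (8^3); erosion leaves 6^3
  expect_equal(sum(m$data), 216)
  expect_true(all(occ1[m$data] & occ2[m$data]))
})

test_that("volume-intensity regression recovers planted slopes and calibrates", {
  set.seed(15)
  groups <- rep(c("young", "old"), each = 20)
  x <- stats::runif(40, 0.4, 0.9)
  y <- 500 - 50 * x + stats::rnorm(40, 0, 1)
  rec <- data.frame(volume = y, intensity = x, group = groups)
  fit <- group_intensity_regression(rec)
  pooled <- fit[fit$group == "pooled", ]
  expect_lt(abs(pooled$slope - (-50)) / 50, 0.1)
  expect_true(pooled$significant)
  expect_equal(nrow(fit), 3)

  # null calibration of the slope significance flag
  set.seed(16)
  hits <- vapply(1:200, function(i) {
    d <- data.frame(volume = stats::rnorm(12, 500, 20),
                    intensity = stats::runif(12), group = "g")
    group_intensity_regression(d)[1, "significant"]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.04)

  expect_error(group_intensity_regression(
    data.frame(volume = 1:4, intensity = c(1, 2, 1, 2),
               group = c("a", "a", "b", "b"))), "fewer than 3")
  expect_error(group_intensity_regression(
    data.frame(volume = 1:3, intensity = rep(1, 3), group = "a")),
    "degenerate")
})
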