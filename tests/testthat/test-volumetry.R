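test_that("in-plane resolution is field of view over matrix size", {
  # the study acquisition: 320 mm FOV on a 256 matrix
  expect_equal(in_plane_resolution(320, 256), 1.25)
  expect_equal(in_plane_resolution(256, 256), 1)
  expect_equal(in_plane_resolution(100, 400), 0.25)
  expect_error(in_plane_resolution(0, 256), "positive")
  expect_error(in_plane_resolution(320, -1), "positive")
})

test_that("voxel volume is the product of the spacings", {
  expect_equal(voxel_volume(c(1.25, 1.25, 2)), 3.125)
  expect_equal(voxel_volume(c(1, 1, 1)), 1)
  expect_equal(voxel_volume(c(0.5, 0.5, 0.5)), 0.125)
  expect_error(voxel_volume(c(1, 1)), "three")
  expect_error(voxel_volume(c(1, 0, 1)), "positive")
})

test_that("tissue volumes are voxel counts times voxel volume in cm^3", {
  arr <- array(0L, dim = c(20, 20, 20))
  arr[1:10, 1:10, 1:10] <- 2L  # 1000 WM voxels
  seg <- label_volume(arr, c(1.25, 1.25, 2))
  tv <- tissue_volumes(seg)
  expect_equal(tv$volume_cm3[tv$tissue == "wm"], 1000 * 3.125 / 1000)
  expect_true(all(tv$volume_cm3[tv$tissue != "wm"] == 0))

  # all-background volume: every tissue zero
  tv0 <- tissue_volumes(label_volume(array(0L, dim = c(5, 5, 5)), c(1, 1, 1)))
  expect_true(all(tv0$volume_cm3 == 0))

  # unknown labels ignored with a warning
  arr[1, 1, 1] <- 99L
  expect_warning(tissue_volumes(label_volume(arr, c(1, 1, 1))), "ignoring")
})

test_that("digitized sphere volume matches the closed form within 2%", {
  seg <- ball_volume(30, 1)
  seg$data[seg$data == 1L] <- 2L
  tv <- tissue_volumes(seg)
  expect_equal(tv$volume_cm3[tv$tissue == "wm"], 4 / 3 * pi * 27,
               tolerance = 0.02)
})

test_that("volumes are additive over disjoint masks and scale with spacing", {
  arr <- array(sample(0:3, 12^3, replace = TRUE), dim = c(12, 12, 12))
  seg1 <- label_volume(arr, c(1, 1, 1))
  seg2 <- label_volume(arr, c(2, 2, 2))
  masks <- hemisphere_masks(seg1)
  whole <- tissue_volumes(seg1)
  left <- tissue_volumes(seg1, hemisphere_mask = masks$left)
  right <- tissue_volumes(seg1, hemisphere_mask = masks$right)
  expect_equal(left$volume_cm3 + right$volume_cm3, whole$volume_cm3)
  # doubling every spacing multiplies volumes by exactly 8
  expect_equal(tissue_volumes(seg2)$volume_cm3, whole$volume_cm3 * 8)
})
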