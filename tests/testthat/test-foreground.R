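test_that("threshold is strict and intensities are 255 * field rounded", {
  arr <- array(0, dim = c(1, 1, 4))
  arr[1, 1, ] <- c(0.5, 0.500001, 0.6, 1)
  fg <- extract_foreground_points(voxel_volume(arr), 0.5)
  expect_equal(nrow(fg$points), 3)              # 0.5 itself is excluded
  expect_equal(fg$intensity, as.integer(round(255 * c(0.500001, 0.6, 1))))
  expect_equal(fg$intensity[2], 153L)           # 0.6 -> 153
  # every kept point satisfies the epsilon0 = 128 bridge
  expect_true(all(fg$intensity >= 128))
})

test_that("coordinates are global (offset applied) and ordered x,y,z", {
  arr <- array(0, dim = c(2, 3, 4))              # (z, y, x)
  arr[2, 3, 4] <- 0.9
  fg <- extract_foreground_points(voxel_volume(arr, offset = c(10L, 20L, 30L)))
  expect_equal(unname(fg$points[1, ]), c(3 + 10, 2 + 20, 1 + 30))
})

test_that("8-bit segmentations are accepted directly", {
  arr <- array(0, dim = c(1, 1, 3))
  arr[1, 1, ] <- c(100, 128, 200)
  fg <- extract_foreground_points(voxel_volume(arr), 0.5)
  expect_equal(nrow(fg$points), 2)               # > 127.5 kept
  expect_equal(fg$intensity, c(128L, 200L))
})

test_that("out-of-range fields are rejected", {
  expect_error(extract_foreground_points(
    voxel_volume(array(-0.1, dim = c(1, 1, 1)))), "must lie")
  expect_error(extract_foreground_points(
    voxel_volume(array(256, dim = c(1, 1, 1)))), "must lie")
})

test_that("empty foreground yields an empty point set", {
  fg <- extract_foreground_points(voxel_volume(array(0.1, dim = c(2, 2, 2))))
  expect_equal(nrow(fg$points), 0)
  expect_equal(nrow(foreground_table(fg)), 0)
})
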