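test_that("uint8 volume round trips bit-exactly with offset", {
  set.seed(1)
  arr <- array(sample(0:255, 4 * 5 * 6, replace = TRUE), dim = c(4, 5, 6))
  vol <- voxel_volume(arr, offset = c(10L, 20L, 30L))
  path <- tempfile(fileext = ".tif")
  write_volume(vol, path, dtype = "uint8")
  back <- read_volume(path)
  expect_identical(round(back$data), round(vol$data))
  expect_true(all(back$data == vol$data))
  expect_equal(back$offset, c(10L, 20L, 30L))
  unlink(c(path, paste0(path, ".meta")))
})

test_that("uint16 volume round trips bit-exactly", {
  set.seed(2)
  arr <- array(sample(0:65535, 3 * 4 * 5, replace = TRUE), dim = c(3, 4, 5))
  vol <- voxel_volume(arr)
  path <- tempfile(fileext = ".tif")
  write_volume(vol, path, dtype = "uint16")
  back <- read_volume(path)
  expect_true(all(back$data == vol$data))
  unlink(c(path, paste0(path, ".meta")))
})

test_that("writer validates dtype range", {
  vol <- voxel_volume(array(300, dim = c(2, 2, 2)))
  path <- tempfile(fileext = ".tif")
  expect_error(write_volume(vol, path, dtype = "uint8"), "must be integers")
})

test_that("voxel_volume validates its inputs", {
  expect_error(voxel_volume(matrix(0, 2, 2)), "3D")
  expect_error(voxel_volume(array(0, dim = c(2, 2, 2)), offset = c(1, 2)),
               "3-vector")
})
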