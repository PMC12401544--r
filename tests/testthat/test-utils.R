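test_that("resample_polyline keeps endpoints and spacing", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0))
  rs <- resample_polyline(pts, spacing = 1)
  expect_equal(unname(rs[1, ]), c(0, 0, 0))
  expect_equal(unname(rs[nrow(rs), ]), c(10, 0, 0))
  gaps <- sqrt(rowSums(diff(rs)^2))
  expect_true(all(gaps <= 1 + 1e-9))
  expect_true(all(gaps > 0))
})

test_that("resample_polyline handles multi-segment curves", {
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
  rs <- resample_polyline(pts, spacing = 0.5)
  gaps <- sqrt(rowSums(diff(rs)^2))
  expect_true(all(gaps <= 0.5 + 1e-9))
  # every resampled point lies on the original polyline
  on_seg <- function(p) {
    (abs(p[3]) < 1e-9) &&
      ((abs(p[2]) < 1e-9 && p[1] >= -1e-9 && p[1] <= 3 + 1e-9) ||
       (abs(p[1] - 3) < 1e-9 && p[2] >= -1e-9 && p[2] <= 4 + 1e-9))
  }
  expect_true(all(apply(rs, 1, on_seg)))
})

test_that("resample_polyline of single point returns it", {
  pts <- matrix(c(1, 2, 3), ncol = 3)
  expect_equal(resample_polyline(pts, 1), pts)
})
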