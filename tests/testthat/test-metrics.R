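test_that("precision/recall/f1 reproduce hand-computed values", {
  # truth: 8 points on a line; recon: 6 matching + 2 stray -> p = 0.75
  truth <- cbind(0:7, 0, 0)
  recon <- rbind(cbind(0:5, 0.5, 0), c(100, 0, 0), c(101, 0, 0))
  m <- precision_recall_f1(recon, truth, match_tol = 4)
  expect_equal(m$precision, 6 / 8)
  expect_equal(m$recall, 1)            # truth points 6,7 still within 4
  expect_equal(m$f1, 2 * 0.75 * 1 / (0.75 + 1))
  expect_equal(m$tp_count, 6L)
  expect_equal(m$g_count, 8L)
  # asymmetric case: f1 = 2pr/(p+r)
  m2 <- precision_recall_f1(cbind(0:3, 0, 0), truth, match_tol = 1)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 5 / 8)       # points 0..4 within 1 of the recon
  expect_equal(m2$f1, 2 * 1 * (5 / 8) / (1 + 5 / 8))
})

test_that("metrics are monotone in the matching tolerance", {
  set.seed(51)
  truth <- cbind(seq(0, 30, by = 1), 0, 0)
  recon <- truth + matrix(rnorm(nrow(truth) * 3, sd = 1.5), ncol = 3)
  f <- vapply(c(0.5, 1, 2, 4), function(tol) {
    precision_recall_f1(recon, truth, tol)$f1
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("edge cases raise the documented errors", {
  pts <- cbind(0:3, 0, 0)
  expect_error(precision_recall_f1(pts, pts[0, , drop = FALSE]),
               "empty ground truth")
  empty <- precision_recall_f1(pts[0, , drop = FALSE], pts)
  expect_equal(empty$f1, 0)
  expect_error(weighted_neuron_scores(list(), numeric(0)), "no neurons")
  expect_error(weighted_neuron_scores(list(list(precision = 1, recall = 1,
                                                f1 = 1)), 0),
               "total ground-truth weight is zero")
})

test_that("weighted averaging uses ground-truth point counts", {
  s <- list(list(precision = 1, recall = 1, f1 = 1),
            list(precision = 0, recall = 0, f1 = 0))
  w <- c(300, 100)
  avg <- weighted_neuron_scores(s, w)
  expect_equal(avg$precision, 0.75)
  expect_equal(avg$f1, 0.75)
})

test_that("tree pooling assigns each tree to its majority-overlap neuron", {
  # ground truth: two parallel lines; recon: each line split in two trees
  sk <- pointneurite:::gt_skeleton(list(cbind(0:40, 0, 0), cbind(0:40, 20, 0)))
  mk <- function(xs, y) {
    pos <- cbind(xs, y, 0)
    n <- nrow(pos)
    neurite_tree(pos, head = c(0L, seq_len(n - 1)),
                 left = c(seq_len(n - 1) + 1L, 0L), right = integer(n))
  }
  trees <- list(mk(cbind(0:20), 0), mk(cbind(21:40), 0),
                mk(cbind(0:40), 20))
  ev <- evaluate_reconstruction(trees, sk, match_tol = 4)
  expect_equal(ev$tree_assignment, c(1L, 1L, 2L))
  # both fragments pool into neuron 1: full recall despite fragmentation
  expect_equal(ev$per_neuron$recall, c(1, 1))
  expect_equal(ev$weighted$f1, 1)
})

test_that("SNR matches the closed form on a constructed volume", {
  # foreground voxels at 100; background: half at 0, half at 20
  # mean_fg = 100, sd_bg = 10 -> SNR = 10 * log10(100 / 10) = 10 dB
  dims <- c(16, 16, 64)
  arr <- array(0, dim = dims)
  arr[seq(2, length(arr), by = 2)] <- 20
  sk <- pointneurite:::gt_skeleton(list(cbind(8:55, 8, 8)))
  # paint the skeleton line (and nothing else) at 100
  for (x in 8:55) arr[9, 9, x + 1] <- 100
  vol <- voxel_volume(arr)
  masks <- pointneurite:::snr_masks(vol, sk, mask_radius = 3)
  # background excludes the 3-voxel dilation of the skeleton
  got <- pointneurite:::snr_from_masks(vol$data, masks)
  direct <- compute_snr(vol, sk)
  expect_equal(got, direct)
  # independent recomputation from the masks
  bg <- vol$data[masks$bg]
  manual <- 10 * log10(mean(vol$data[masks$fg]) /
                         sqrt(mean((bg - mean(bg))^2)))
  expect_equal(got, manual)
  expect_equal(got, 10, tolerance = 0.2)
})

test_that("SNR error cases", {
  vol <- voxel_volume(array(5, dim = c(4, 4, 4)))
  sk <- pointneurite:::gt_skeleton(list(cbind(0:3, 0, 0)))
  expect_error(compute_snr(vol, sk), "zero background standard deviation")
})
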