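test_that("phantom generation is deterministic for a fixed seed", {
  sp <- phantom_spec(shape = c(64, 64, 64), n_neurites = 3, rng_seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$skeleton$polylines, b$skeleton$polylines)
})

test_that("two parallel neurites give exactly two skeleton components", {
  sp <- phantom_spec(shape = c(64, 64, 64), n_neurites = 2,
                     n_parallel_pairs = 1, parallel_gap = 2, rng_seed = 1)
  ph <- generate_phantom(sp)
  expect_length(ph$skeleton$polylines, 2)
  # parallel corridor: centerline distance ~ 2*radius + gap over >= 30 voxels
  G <- lapply(ph$skeleton$polylines, resample_polyline, spacing = 1)
  d <- pointneurite:::cpp_nn_within(G[[1]], G[[2]], 100)$dist
  expect_gte(sum(abs(d - 8) < 1), 30)
})

test_that("crossing pairs intersect at the requested angle", {
  for (ang in c(30, 60, 90)) {
    sp <- phantom_spec(shape = c(96, 96, 96), n_neurites = 2, n_crossings = 1,
                       crossing_angles = ang, rng_seed = 2)
    ph <- generate_phantom(sp)
    G <- lapply(ph$skeleton$polylines, resample_polyline, spacing = 1)
    # the curves intersect (within 2*radius)
    d <- pointneurite:::cpp_nn_within(G[[1]], G[[2]], 100)$dist
    expect_lt(min(d), 2 * sp$neurite_radius)
    # angle between the chords near the crossing matches the request
    i <- which.min(d)
    j <- pointneurite:::cpp_nn_within(G[[1]][i, , drop = FALSE], G[[2]],
                                      100)$index[1]
    span <- 10
    c1 <- G[[1]][min(i + span, nrow(G[[1]])), ] - G[[1]][max(i - span, 1), ]
    c2 <- G[[2]][min(j + span, nrow(G[[2]])), ] - G[[2]][max(j - span, 1), ]
    got <- acos(min(1, abs(sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))))) * 180 / pi
    expect_lt(abs(got - ang), 15)
  }
})

test_that("tube voxels carry the foreground intensity", {
  sp <- phantom_spec(shape = c(48, 48, 48), n_neurites = 1, rng_seed = 3)
  ph <- generate_phantom(sp)
  expect_equal(max(ph$volume$data), sp$foreground_intensity)
  # voxels near the centerline are foreground
  p <- ph$skeleton$polylines[[1]][1, ]
  v <- round(p)
  expect_equal(ph$volume$data[v[3] + 1, v[2] + 1, v[1] + 1],
               sp$foreground_intensity)
})

test_that("SNR calibration round trips within 0.5 dB", {
  sp <- phantom_spec(shape = c(64, 64, 64), n_neurites = 3, target_snr = 10,
                     rng_seed = 4)
  ph <- generate_phantom(sp)
  got <- compute_snr(ph$volume, ph$skeleton)
  expect_lt(abs(got - 10), 0.5)
})

test_that("distance-field labels peak on the skeleton and vanish far away", {
  sp <- phantom_spec(shape = c(48, 48, 48), n_neurites = 1, rng_seed = 6)
  ph <- generate_phantom(sp)
  field <- make_distance_field_labels(ph$skeleton, c(48, 48, 48))
  expect_equal(max(field$data), 1)
  expect_equal(min(field$data), 0)
  p <- round(ph$skeleton$polylines[[1]][5, ])
  expect_gt(field$data[p[3] + 1, p[2] + 1, p[1] + 1], 0.5)
})

test_that("branch phantom is deterministic and rooted at node 1", {
  a <- generate_branch_phantom(n_steps = 40, n_bifurcations = 2, rng_seed = 9)
  b <- generate_branch_phantom(n_steps = 40, n_bifurcations = 2, rng_seed = 9)
  expect_identical(a$tree$pos, b$tree$pos)
  expect_equal(a$root, 1L)
  expect_equal(pointneurite:::tree_root(a$tree), 1L)
  # two bifurcations -> two nodes with two children
  both <- sum(a$tree$left > 0 & a$tree$right > 0)
  expect_equal(both, 2)
})

test_that("pair configurations fail loudly when the block is too small", {
  expect_error(phantom_spec(shape = c(64, 64, 64), n_neurites = 1,
                            n_crossings = 1),
               "more neurites")
})
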