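# A small straight tube of foreground points used by several tests.
make_tube_points <- function(len = 40, rad = 2) {
  g <- expand.grid(x = 0:len, y = -rad:rad, z = -rad:rad)
  g <- g[g$y^2 + g$z^2 <= rad^2, ]
  as.matrix(g)
}

test_that("density counts neighbors within the cutoff radius", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.5, 0, 0), c(10, 0, 0))
  d <- compute_density(pts, cutoff_radius = 3)
  expect_equal(d, c(2, 2, 2, 0))     # neighbor counts exclude the point itself
  expect_error(compute_density(pts[0, , drop = FALSE]), "empty point set")
})

test_that("seed selection starts at the density median and excludes by radius", {
  pts <- make_tube_points()
  dens <- compute_density(pts, 3)
  sel <- select_seeds(pts, dens, exclusion_radius = 5)
  expect_equal(sel$K, length(sel$seeds))
  expect_gt(sel$K, 2)
  # first seed is the median-density point in the stable ascending order
  ord <- order(dens, seq_len(nrow(pts)))
  expect_equal(sel$seeds[1], ord[ceiling(nrow(pts) / 2)])
  # no two seeds closer than the exclusion radius
  S <- pts[sel$seeds, , drop = FALSE]
  dd <- as.matrix(dist(S))
  diag(dd) <- Inf
  expect_gte(min(dd), 5)
  # seeds cover the tube: every point is near some seed
  cov <- pointneurite:::cpp_nn_within(pts, S, 100)$dist
  expect_lt(max(cov), 5 + 1e-9)
})

test_that("constrained GMM satisfies its published constraints", {
  pts <- make_tube_points()
  ints <- rep(255L, nrow(pts))
  sel <- select_seeds(pts, compute_density(pts, 3), 5)
  cls <- fit_constrained_gmm(pts, ints, sel$seeds)
  expect_gt(length(cls), 0)
  # mixture weights sum to one
  expect_equal(sum(vapply(cls, `[[`, numeric(1), "pi")), 1)
  # determinant constraint: det(Sigma) <= (3 * 6)^3
  dets <- vapply(cls, function(cl) det(cl$sigma), numeric(1))
  expect_true(all(dets <= 5832 * (1 + 1e-8)))
  # every cluster center rounds onto a foreground voxel (intensity >= 128)
  lookup <- pointneurite:::make_intensity_lookup(pts, ints)
  cints <- vapply(cls, function(cl) lookup(cl$mu), numeric(1))
  expect_true(all(cints >= 128))
  # members partition the point set
  mem <- sort(unlist(lapply(cls, `[[`, "members")))
  expect_equal(mem, seq_len(nrow(pts)))
})

test_that("hard assignment splits 26-disconnected members", {
  # two far-apart blobs but a single seed: the final labeling must still
  # yield spatially connected clusters
  a <- make_tube_points(len = 6)
  b <- sweep(a, 2, c(60, 0, 0), "+")
  pts <- rbind(a, b)
  ints <- rep(255L, nrow(pts))
  cls <- fit_constrained_gmm(pts, ints, seeds = c(1L, nrow(a) + 1L))
  for (cl in cls) {
    vox <- round(pts[cl$members, , drop = FALSE])
    labs <- pointneurite:::cpp_label_components26(vox)
    expect_equal(length(unique(labs)), 1)
  }
})

test_that("consolidation merges tube sections but not parallel tubes", {
  # one tube over-segmented into four abutting quarters -> one cluster
  pts <- make_tube_points(len = 39)
  quarters <- split(seq_len(nrow(pts)), cut(pts[, 1], 4, labels = FALSE))
  cls <- lapply(quarters, function(ix) {
    list(members = as.integer(ix), pi = length(ix) / nrow(pts),
         mu = colMeans(pts[ix, , drop = FALSE]),
         sigma = pointneurite:::empirical_cov(pts[ix, , drop = FALSE]))
  })
  merged <- merge_lateral_duplicates(cls, pts)
  expect_length(merged, 1)
  expect_equal(sort(merged[[1]]$members), seq_len(nrow(pts)))

  # two parallel tubes 8 apart, each split in two -> merging may join along
  # each tube but must never mix the tubes
  p1 <- make_tube_points(len = 39)
  p2 <- sweep(p1, 2, c(0, 8, 0), "+")
  pts2 <- rbind(p1, p2)
  halves <- list(which(pts2[, 1] < 20 & pts2[, 2] < 4),
                 which(pts2[, 1] >= 20 & pts2[, 2] < 4),
                 which(pts2[, 1] < 20 & pts2[, 2] >= 4),
                 which(pts2[, 1] >= 20 & pts2[, 2] >= 4))
  cls2 <- lapply(halves, function(ix) {
    list(members = as.integer(ix), pi = length(ix) / nrow(pts2),
         mu = colMeans(pts2[ix, , drop = FALSE]),
         sigma = pointneurite:::empirical_cov(pts2[ix, , drop = FALSE]))
  })
  merged2 <- merge_lateral_duplicates(cls2, pts2)
  for (cl in merged2) {
    ys <- pts2[cl$members, 2]
    expect_true(all(ys < 4) || all(ys >= 4))
  }
})

test_that("cluster_table summarizes clusters", {
  pts <- make_tube_points(len = 10)
  cls <- list(list(members = seq_len(nrow(pts)), pi = 1,
                   mu = colMeans(pts),
                   sigma = pointneurite:::empirical_cov(pts)))
  tab <- cluster_table(cls)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("cluster", "pi", "mu_x", "mu_y", "mu_z") %in% names(tab)))
})
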