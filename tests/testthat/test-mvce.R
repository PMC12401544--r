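test_that("solver matches the Khachiyan oracle on 20 random clouds", {
  set.seed(11)
  for (rep in 1:20) {
    pts <- matrix(rnorm(30 * 3, sd = runif(1, 1, 6)), ncol = 3)
    pts <- sweep(pts, 2, runif(3, -20, 20), "+")
    got <- solve_mvce(pts)
    ref <- khachiyan_mvce(pts)
    v_got <- ellipsoid_volume(got$Q)
    v_ref <- ellipsoid_volume(ref$Q)
    # volumes within 1 percent of the independent oracle
    expect_lt(abs(v_got - v_ref) / v_ref, 0.01)
    # every point covered up to 1e-6
    q <- rowSums((sweep(pts, 2, got$center) %*% got$Q) *
                   sweep(pts, 2, got$center))
    expect_lte(max(q), 1 + 1e-6)
  }
})

test_that("active-set path agrees with the core solver on large clouds", {
  set.seed(12)
  pts <- matrix(rnorm(400 * 3, sd = 3), ncol = 3)
  pts[, 1] <- pts[, 1] * 5                      # elongated cloud
  a <- solve_mvce(pts)                          # m > 120 -> active set
  b <- pointneurite:::solve_mvce_core(pts)
  expect_lt(abs(ellipsoid_volume(a$Q) - ellipsoid_volume(b$Q)) /
              ellipsoid_volume(b$Q), 0.01)
  q <- rowSums((sweep(pts, 2, a$center) %*% a$Q) * sweep(pts, 2, a$center))
  expect_lte(max(q), 1 + 1e-6)
})

test_that("degenerate inputs raise the documented condition classes", {
  line <- cbind(0:9, 0, 0)
  expect_error(solve_mvce(line), class = "pn_degenerate")
  expect_error(solve_mvce(line), "rank < 3")
  plane <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(solve_mvce(plane), class = "pn_degenerate")
})

test_that("axis endpoints lie on the boundary along the longest axis", {
  Q <- diag(c(1 / 25, 1 / 4, 1))                # semi-axes 5, 2, 1
  ctr <- c(3, -1, 2)
  e <- ellipsoid_axis_endpoints(Q, ctr)
  expect_equal(e$t0, ctr + c(5, 0, 0))
  expect_equal(e$t1, ctr - c(5, 0, 0))
  for (p in list(e$t0, e$t1)) {
    expect_equal(as.numeric(t(p - ctr) %*% Q %*% (p - ctr)), 1)
  }
  expect_error(ellipsoid_axis_endpoints(diag(c(1, 1, -1)), ctr),
               "positive definite")
})

test_that("characterize_cluster covers members and splits bent clusters", {
  # straight tube -> a single covering ellipsoid aligned with the tube
  set.seed(21)
  g <- expand.grid(x = 0:30, y = -1:1, z = -1:1)
  pts <- as.matrix(g) + matrix(rnorm(nrow(g) * 3, sd = 0.05), ncol = 3)
  cl <- list(members = seq_len(nrow(pts)))
  es <- characterize_cluster(cl, pts, cluster_id = 7)
  expect_length(es, 1)
  ax <- es[[1]]$t1 - es[[1]]$t0
  expect_gt(abs(ax[1]) / sqrt(sum(ax^2)), 0.99)
  expect_equal(es[[1]]$cluster_id, 7)
  q <- rowSums((sweep(pts, 2, es[[1]]$center) %*% es[[1]]$Q) *
                 sweep(pts, 2, es[[1]]$center))
  expect_lte(max(q), 1 + 1e-4)

  # right-angle elbow of voxel tubes: a single ellipsoid cannot represent
  # it, the solver recurses into a covering set of smaller ellipsoids
  arm1 <- expand.grid(x = 0:20, y = -1:1, z = -1:1)
  arm2 <- expand.grid(x = -1:1, y = 1:20, z = -1:1)
  bent <- as.matrix(rbind(arm1, arm2))
  cl2 <- list(members = seq_len(nrow(bent)))
  es2 <- characterize_cluster(cl2, bent)
  expect_gte(length(es2), 2)
  # union of coverage: each point inside at least one ellipsoid
  covered <- rep(FALSE, nrow(bent))
  for (e in es2) {
    qq <- rowSums((sweep(bent, 2, e$center) %*% e$Q) * sweep(bent, 2, e$center))
    covered <- covered | qq <= 1 + 1e-4
  }
  expect_true(all(covered))
})

test_that("degenerate clusters become thin ellipsoids with extreme endpoints", {
  pts <- cbind(seq(0, 12, by = 1), 0, 0)
  cl <- list(members = seq_len(nrow(pts)))
  es <- characterize_cluster(cl, pts)
  expect_length(es, 1)
  ends <- rbind(es[[1]]$t0, es[[1]]$t1)
  expect_equal(sort(ends[, 1]), c(0, 12), tolerance = 1e-6)
})

test_that("ellipsoid_table lists centers and endpoints", {
  e <- pointneurite:::new_ellipsoid(c(0, 0, 0), diag(3), cluster_id = 1)
  tab <- ellipsoid_table(list(e))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("c_x", "t0_x", "t1_x", "q_xx") %in% names(tab)))
})
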