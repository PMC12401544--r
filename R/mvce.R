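#' Minimum-volume covering ellipsoid of a point set
#'
#' Solves the MVCE problem `min -log det(A)` s.t. `||A x_i - y|| <= 1` with a
#' primal-dual barrier method: the dual multipliers `d` and slacks `z` are
#' updated along Newton directions for the barrier-perturbed optimality
#' system, with barrier `theta = d'z / (10 m)` and a 0.99 fraction-to-boundary
#' step, starting from `d0 = 3/(2m)`.  The returned shape matrix is rescaled
#' (by at most `1 + 1e-6`) so that every input point satisfies the covering
#' inequality exactly.
#'
#' @param points m x 3 matrix, m >= 4 affinely independent rows.
#' @param feas_tol primal feasibility tolerance.
#' @param gap_tol duality-gap tolerance (relative to the objective scale).
#' @param max_newton_iter iteration cap.
#' @param cluster_id identifier carried on the result.
#' @return an `ellipsoid`: list with `center`, `Q` (SPD shape matrix of the
#'   quadratic form `(x-c)'Q(x-c) <= 1`), longest-axis endpoints `t0`, `t1`,
#'   and `cluster_id`.
#' @export
solve_mvce <- function(points, feas_tol = 1e-7, gap_tol = 1e-7,
                       max_newton_iter = 200, cluster_id = NA) {
  pts <- unique_rows_num(as.matrix(points))
  m <- nrow(pts)
  if (m < 4 || point_rank(pts) < 3) {
    stop(degenerate_condition("points are affinely dependent (rank < 3)"))
  }
  if (m > 120) {
    return(solve_mvce_active_set(pts, feas_tol, gap_tol, max_newton_iter,
                                 cluster_id))
  }
  solve_mvce_core(pts, feas_tol, gap_tol, max_newton_iter, cluster_id)
}

# The optimal ellipsoid is supported by at most d(d+3)/2 = 9 extreme points,
# so for large clusters the dense Newton system (m x m) is solved on a small
# working subset that is grown with covering violators until none remain;
# the result is identical (to tolerance) to solving on all points.
solve_mvce_active_set <- function(pts, feas_tol, gap_tol, max_newton_iter,
                                  cluster_id) {
  m <- nrow(pts)
  dirs <- rbind(diag(3), -diag(3),
                expand_signs(c(1, 1, 1) / sqrt(3)))
  idx <- unique(c(apply(pts %*% t(dirs), 2, which.max),
                  seq(1, m, by = max(1, floor(m / 40)))))
  for (round in seq_len(60)) {
    ell <- tryCatch(
      solve_mvce_core(pts[idx, , drop = FALSE], feas_tol, gap_tol,
                      max_newton_iter, cluster_id),
      pn_degenerate = function(e) NULL)
    if (is.null(ell)) {  # working subset collapsed to a plane: densify it
      idx <- unique(c(idx, seq(1, m, by = max(1, floor(m / 120)))))
      next
    }
    diffs <- sweep(pts, 2, ell$center)
    q <- rowSums((diffs %*% ell$Q) * diffs)
    viol <- which(q > 1 + 1e-6)
    if (length(viol) == 0) {
      maxq <- max(q)
      if (maxq > 1) {
        ell <- new_ellipsoid(ell$center, ell$Q / maxq, cluster_id)
      }
      return(ell)
    }
    add <- viol[order(q[viol], decreasing = TRUE)][seq_len(min(24,
                                                               length(viol)))]
    idx <- unique(c(idx, add))
  }
  solve_mvce_core(pts, feas_tol, gap_tol, max_newton_iter, cluster_id)
}

expand_signs <- function(v) {
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  sweep(s, 2, v, "*")
}

solve_mvce_core <- function(points, feas_tol = 1e-7, gap_tol = 1e-7,
                            max_newton_iter = 200, cluster_id = NA) {
  pts <- unique_rows_num(as.matrix(points))
  m <- nrow(pts)
  if (m < 4 || point_rank(pts) < 3) {
    stop(degenerate_condition("points are affinely dependent (rank < 3)"))
  }
  Xt <- t(pts)  # 3 x m
  e <- rep(1, m)
  d <- rep(3 / (2 * m), m)
  fd <- mvce_f(Xt, d)
  z <- pmax(e - fd, 1e-8)

  converged <- FALSE
  for (it in seq_len(max_newton_iter)) {
    fd <- mvce_f(Xt, d)
    M <- mvce_M(Xt, d)
    detA <- 1 / sqrt(det(M))
    feas <- sqrt(sum((e - fd - z)^2))
    gap <- abs(sum(d * z) / (-detA))
    if (feas <= feas_tol && gap <= gap_tol) {
      converged <- TRUE
      break
    }
    theta <- sum(d * z) / (10 * m)
    dir <- newton_direction(list(X = Xt, d = d, z = z, theta = theta))
    beta_bar <- step_to_boundary(d, z, dir$dd, dir$dz)
    beta <- min(0.99 * beta_bar, 1)
    d <- d + beta * dir$dd
    z <- z + beta * dir$dz
  }
  if (!converged) {
    stop(solver_condition(sprintf(
      "MVCE solver did not converge in %d iterations (feasibility %.3g, gap %.3g)",
      max_newton_iter, feas, gap)))
  }

  M <- mvce_M(Xt, d)
  Q <- solve(M)
  Q <- (Q + t(Q)) / 2
  ctr <- as.numeric(Xt %*% d) / sum(d)
  # guarantee exact covering (solver tolerance can leave ~1e-8 violations)
  diffs <- sweep(pts, 2, ctr)
  maxq <- max(rowSums((diffs %*% Q) * diffs))
  if (maxq > 1) Q <- Q / maxq
  new_ellipsoid(ctr, Q, cluster_id)
}

# M(d) = 2 * sum_i d_i (x_i - xc)(x_i - xc)', so that A^{-2} = M.
mvce_M <- function(Xt, d) {
  xc <- as.numeric(Xt %*% d) / sum(d)
  B <- Xt - xc
  2 * (B %*% (d * t(B)))
}

# f_i(d) = (x_i - xc)' M(d)^{-1} (x_i - xc)
mvce_f <- function(Xt, d) {
  xc <- as.numeric(Xt %*% d) / sum(d)
  B <- Xt - xc
  Minv <- solve(mvce_M(Xt, d))
  colSums(B * (Minv %*% B))
}

#' Newton direction of the MVCE barrier system
#'
#' Computes the Newton step for the system `f(d) + z = e`, `Dz = theta e`
#' at the state `(d, z, theta)`: the Jacobian of `f` is
#' `-2 (Sigma / e'd + Sigma o Sigma)` with `Sigma = B' A^2 B` the Gram matrix
#' of the centered points under the current metric.
#'
#' @param state list with `X` (3 x m data matrix), `d`, `z` (positive
#'   m-vectors) and `theta` (barrier parameter).
#' @return list with components `dd` and `dz`.
#' @export
newton_direction <- function(state) {
  Xt <- state$X
  d <- state$d
  z <- state$z
  theta <- state$theta
  m <- length(d)
  xc <- as.numeric(Xt %*% d) / sum(d)
  B <- Xt - xc
  M <- mvce_M(Xt, d)
  A2 <- solve(M)
  Sig <- crossprod(B, A2 %*% B)          # m x m
  grad <- -2 * (Sig / sum(d) + Sig * Sig)
  fd <- colSums(B * (A2 %*% B))
  h1 <- 1 - z - fd
  h2 <- theta - d * z
  J <- grad - diag(z / d, m)
  dd <- tryCatch(solve(J, h1 - h2 / d), error = function(e) {
    stop(solver_condition("singular Newton system in MVCE solver"))
  })
  dz <- h2 / d - (z / d) * dd
  list(dd = dd, dz = dz)
}

step_to_boundary <- function(d, z, dd, dz) {
  ratios <- c(ifelse(dd < 0, -d / dd, Inf), ifelse(dz < 0, -z / dz, Inf))
  min(ratios, 1e12)
}

degenerate_condition <- function(msg) {
  structure(class = c("pn_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

solver_condition <- function(msg) {
  structure(class = c("pn_solver_error", "error", "condition"),
            list(message = msg, call = NULL))
}

unique_rows_num <- function(m) m[!duplicated(round(m, 9)), , drop = FALSE]

point_rank <- function(pts, tol = 1e-7) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv, 1))
}

new_ellipsoid <- function(center, Q, cluster_id = NA) {
  ends <- ellipsoid_axis_endpoints(Q, center)
  structure(list(center = as.numeric(center), Q = Q,
                 t0 = ends$t0, t1 = ends$t1, cluster_id = cluster_id),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid: center (%.2f, %.2f, %.2f), axis length %.2f>\n",
              x$center[1], x$center[2], x$center[3],
              vnorm(x$t1 - x$t0)))
  invisible(x)
}

#' Endpoints of an ellipsoid's longest axis
#'
#' For the ellipsoid `(x-c)'Q(x-c) <= 1` the longest semi-axis is
#' `1/sqrt(lambda_min(Q))` along the corresponding unit eigenvector `v`; the
#' eigenvector sign is fixed so its first nonzero component is positive.
#'
#' @param Q SPD shape matrix.
#' @param center ellipsoid center.
#' @return list with `t0 = c + v/sqrt(lambda_min)` and `t1 = c - ...`.
#' @export
ellipsoid_axis_endpoints <- function(Q, center) {
  eg <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  lam <- eg$values[3]
  if (lam <= 0) stop("shape matrix is not positive definite")
  v <- eg$vectors[, 3]
  nz <- which(abs(v) > 1e-12)[1]
  if (v[nz] < 0) v <- -v
  a <- 1 / sqrt(lam)
  list(t0 = center + a * v, t1 = center - a * v)
}

#' Characterize a cluster by covering ellipsoids
#'
#' Solves the MVCE of the cluster's member points.  If the solved center
#' falls outside the members' convex hull (a bent cluster) the cluster is
#' split in two by a local two-component Gaussian mixture and each part is
#' characterized recursively (depth-capped).  Degenerate clusters (fewer than
#' 4 points, or collinear) are represented by a thin ellipsoid whose axis
#' endpoints are the extreme member points; planar clusters are inflated with
#' tiny jitter along the null direction before solving.
#'
#' @param cluster a cluster from [fit_constrained_gmm()].
#' @param points the full foreground point matrix the cluster indexes into.
#' @param config the `mvce` section of [pn_config()].
#' @param cluster_id identifier stamped on the resulting ellipsoids.
#' @param depth recursion depth (internal).
#' @return list of `ellipsoid` objects, each covering its own subset.
#' @export
characterize_cluster <- function(cluster, points, config = pn_config()$mvce,
                                 cluster_id = NA, depth = 0) {
  pts <- points[cluster$members, , drop = FALSE]
  upts <- unique_rows_num(pts)
  rk <- if (nrow(upts) > 1) point_rank(upts) else 0

  if (nrow(upts) < 3 || rk < 2) {
    seg <- segment_ellipsoid(upts, cluster_id)
    seg$members <- cluster$members
    return(list(seg))
  }
  solve_pts <- upts
  if (rk == 2) {
    # planar: inflate along the null direction so the solver sees rank 3
    ctr <- colMeans(upts)
    sv <- svd(sweep(upts, 2, ctr))
    nullv <- sv$v[, 3]
    solve_pts <- rbind(upts + 1e-3 * matrix(nullv, nrow(upts), 3, byrow = TRUE),
                       upts - 1e-3 * matrix(nullv, nrow(upts), 3, byrow = TRUE))
  }

  ell <- tryCatch(
    solve_mvce(solve_pts, feas_tol = config$feas_tol,
               gap_tol = config$gap_tol,
               max_newton_iter = config$max_newton_iter,
               cluster_id = cluster_id),
    pn_degenerate = function(e) NULL,
    pn_solver_error = function(e) NULL)
  if (!is.null(ell)) ell$members <- cluster$members

  degenerate <- is.null(ell)
  outside <- !degenerate && !hull_contains(upts, ell$center)

  if ((degenerate || outside) && depth < config$split_depth &&
      nrow(upts) > 4) {
    parts <- local_two_split(pts)
    if (!is.null(parts)) {
      sub <- lapply(parts, function(idx) {
        characterize_cluster(list(members = cluster$members[idx]),
                             points, config, cluster_id, depth + 1)
      })
      return(do.call(c, sub))
    }
  }
  if (degenerate) {
    seg <- segment_ellipsoid(upts, cluster_id)
    seg$members <- cluster$members
    return(list(seg))
  }
  if (outside) {
    warning("MVCE center outside the cluster hull at the recursion floor; ",
            "accepting the ellipsoid")
  }
  list(ell)
}

# Thin covering ellipsoid for (near-)collinear clusters: axis endpoints are
# the true extreme points.
segment_ellipsoid <- function(pts, cluster_id = NA) {
  ctr <- colMeans(pts)
  if (nrow(pts) == 1) {
    return(new_ellipsoid(ctr, diag(4, 3), cluster_id))
  }
  sv <- svd(sweep(pts, 2, ctr))
  v1 <- sv$v[, 1]
  proj <- as.numeric(sweep(pts, 2, ctr) %*% v1)
  ctr2 <- ctr + v1 * (max(proj) + min(proj)) / 2
  a <- max((max(proj) - min(proj)) / 2, 0.5) + 1e-6
  resid <- sweep(pts, 2, ctr2) - outer(as.numeric(sweep(pts, 2, ctr2) %*% v1), v1)
  b <- max(sqrt(rowSums(resid^2)), 0.5) + 1e-6
  V <- qr.Q(qr(cbind(v1, diag(3))))[, 1:3]
  if (sum(V[, 1] * v1) < 0) V <- -V
  Q <- V %*% diag(c(1 / a^2, 1 / b^2, 1 / b^2)) %*% t(V)
  diffs <- sweep(pts, 2, ctr2)
  maxq <- max(rowSums((diffs %*% Q) * diffs))
  if (maxq > 1) Q <- Q / maxq
  new_ellipsoid(ctr2, (Q + t(Q)) / 2, cluster_id)
}

# Frank-Wolfe nearest-point iteration on the convex hull with a
# separating-hyperplane certificate: returns FALSE only when a direction u
# with u'c < min_j u'x_j is found.
hull_contains <- function(pts, c0, tol = 1e-7, max_iter = 300) {
  P <- as.matrix(pts)
  d2 <- rowSums(sweep(P, 2, c0)^2)
  y <- P[which.min(d2), ]
  for (it in seq_len(max_iter)) {
    g <- y - c0
    if (sum(g * g) < tol^2) return(TRUE)
    scores <- as.numeric(P %*% g)
    if (min(scores) > sum(g * c0) + 1e-9) return(FALSE)  # separated
    s <- P[which.min(scores), ]
    dir <- s - y
    dd <- sum(dir * dir)
    if (dd < 1e-18) return(TRUE)
    t <- max(0, min(1, sum((c0 - y) * dir) / dd))
    if (t <= 0) return(TRUE)  # no descent: y is the projection, c0 inside face
    y <- y + t * dir
  }
  TRUE
}

# Plain two-component GMM restricted to a member set; returns two index
# vectors (into pts) or NULL when the split degenerates.
local_two_split <- function(pts, iters = 25) {
  m <- nrow(pts)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  v1 <- sv$v[, 1]
  off <- v1 * max(sv$d[1] / sqrt(m), 0.5)
  mu <- rbind(ctr + off, ctr - off)
  sigma <- list(diag(3), diag(3))
  piw <- c(0.5, 0.5)
  for (it in seq_len(iters)) {
    info <- lapply(sigma, cov_to_prec)
    pass <- cpp_gmm_pass(pts, log(piw),
                         mu, do.call(rbind, lapply(info, function(i)
                           as.numeric(t(i$prec)))),
                         vapply(info, function(i) i$logdet, numeric(1)))
    if (any(pass$Nk < 1e-6)) break
    piw <- pass$Nk / sum(pass$Nk)
    mu <- pass$Sx / pass$Nk
    sigma <- lapply(1:2, function(k) {
      s <- matrix(c(pass$Sxx[k, 1], pass$Sxx[k, 4], pass$Sxx[k, 5],
                    pass$Sxx[k, 4], pass$Sxx[k, 2], pass$Sxx[k, 6],
                    pass$Sxx[k, 5], pass$Sxx[k, 6], pass$Sxx[k, 3]), 3, 3) /
        pass$Nk[k] - tcrossprod(mu[k, ])
      (s + t(s)) / 2 + diag(1e-6, 3)
    })
  }
  info <- lapply(sigma, cov_to_prec)
  pass <- cpp_gmm_pass(pts, log(piw), mu,
                       do.call(rbind, lapply(info, function(i)
                         as.numeric(t(i$prec)))),
                       vapply(info, function(i) i$logdet, numeric(1)))
  a <- which(pass$assign == 1)
  b <- which(pass$assign == 2)
  if (length(a) == 0 || length(b) == 0) {
    proj <- as.numeric(sweep(pts, 2, colMeans(pts)) %*% v1)
    a <- which(proj <= stats::median(proj))
    b <- setdiff(seq_len(m), a)
    if (length(a) == 0 || length(b) == 0) return(NULL)
  }
  list(a, b)
}

#' Summarize ellipsoids as a data frame
#'
#' @param ellipsoids list of `ellipsoid` objects.
#' @return data frame with center, shape entries and axis endpoints.
#' @export
ellipsoid_table <- function(ellipsoids) {
  do.call(rbind, lapply(seq_along(ellipsoids), function(i) {
    e <- ellipsoids[[i]]
    data.frame(id = i, cluster_id = e$cluster_id,
               c_x = e$center[1], c_y = e$center[2], c_z = e$center[3],
               q_xx = e$Q[1, 1], q_yy = e$Q[2, 2], q_zz = e$Q[3, 3],
               q_xy = e$Q[1, 2], q_xz = e$Q[1, 3], q_yz = e$Q[2, 3],
               t0_x = e$t0[1], t0_y = e$t0[2], t0_z = e$t0[3],
               t1_x = e$t1[1], t1_y = e$t1[2], t1_z = e$t1[3])
  }))
}
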