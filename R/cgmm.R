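#' Local point density (hard-cutoff kernel)
#'
#' Density of a foreground point is the number of other points within
#' `cutoff_radius` of it, the cutoff-kernel variant of density-peak
#' clustering.
#'
#' @param points n x 3 matrix of point coordinates.
#' @param cutoff_radius neighborhood radius in voxels.
#' @return integer vector of per-point densities.
#' @export
compute_density <- function(points, cutoff_radius = 3) {
  if (nrow(points) == 0) stop("empty point set")
  cpp_radius_count(as.matrix(points), cutoff_radius)
}

#' Select cluster seeds from the density median outward
#'
#' Points are visited starting at the median-density point, then alternating
#' one step below / one step above the median in the density-sorted order.
#' A visited point becomes a seed unless it lies within `exclusion_radius` of
#' an already chosen seed.  Starting at the median avoids seeding at crossover
#' centers (highest density) and at neurite edges (lowest density).
#'
#' @param points n x 3 matrix.
#' @param densities densities from [compute_density()].
#' @param exclusion_radius seed exclusion radius in voxels.
#' @return list with `seeds` (indices into `points`, in visiting order) and
#'   `K` (the seed count).
#' @export
select_seeds <- function(points, densities, exclusion_radius = 5) {
  n <- nrow(points)
  if (n == 0) stop("empty point set")
  ord <- order(densities, seq_len(n))  # ascending density, stable
  m <- ceiling(n / 2)
  below <- rev(seq_len(m - 1))         # m-1, m-2, ..., 1
  above <- seq_len(n - m) + m          # m+1, ..., n
  inter <- integer(0)
  for (i in seq_len(max(length(below), length(above)))) {
    if (i <= length(below)) inter <- c(inter, below[i])
    if (i <= length(above)) inter <- c(inter, above[i])
  }
  pos <- c(m, inter)
  visit <- ord[pos]
  is_seed <- cpp_greedy_seeds(as.matrix(points), as.integer(visit),
                              exclusion_radius)
  seeds <- visit[is_seed[visit]]
  list(seeds = seeds, K = length(seeds))
}

# Integer-voxel intensity lookup (binary search over encoded voxel keys);
# voxels off the foreground have intensity 0.
make_intensity_lookup <- function(points, intensities) {
  pts <- round_voxels(points)
  origin <- apply(pts, 2, min)
  spanv <- apply(pts, 2, max) - origin + 1
  keys <- (pts[, 1] - origin[1]) +
    spanv[1] * ((pts[, 2] - origin[2]) + spanv[2] * (pts[, 3] - origin[3]))
  ord <- order(keys)
  skeys <- keys[ord]
  sint <- intensities[ord]
  function(p) {
    q <- round(p) - origin
    if (any(q < 0) || any(q >= spanv)) return(0)
    k <- q[1] + spanv[1] * (q[2] + spanv[2] * q[3])
    i <- findInterval(k, skeys)
    if (i > 0 && skeys[i] == k) sint[i] else 0
  }
}

cov_to_prec <- function(sigma) {
  for (ridge in c(0, 1e-6, 1e-4, 1e-2)) {
    s <- sigma + diag(ridge, 3)
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(prec = chol2inv(ch), logdet = 2 * sum(log(diag(ch))),
                  sigma = s))
    }
  }
  stop("covariance matrix could not be regularized")
}

#' Fit the constrained Gaussian mixture model
#'
#' EM over a K-component Gaussian mixture initialized at the seed positions
#' (identity covariances, uniform weights), with two constraints enforced
#' after every M-step: a component whose center falls on a voxel with
#' intensity below `epsilon0` is replaced by two daughters displaced half a
#' standard deviation along its principal eigenvector, and a component whose
#' covariance determinant exceeds `epsilon1 = (3 * neurite_diameter)^3` is
#' rescaled so the determinant equals `epsilon1` (cube-root factor; the
#' literal linear factor is available via `literal_det_rescale`).  After
#' convergence every point is hard-assigned to its maximum-responsibility
#' component, clusters are split into 26-connected components, and centers are
#' recursively split until they all sit on foreground voxels.
#'
#' @param points n x 3 matrix of foreground voxel coordinates.
#' @param intensities 8-bit intensities of the points.
#' @param seeds indices of the initial component centers (from
#'   [select_seeds()]).
#' @param config the `cgmm` section of [pn_config()].
#' @return list of clusters; each has `members` (point indices), `pi`, `mu`
#'   and `sigma`.
#' @export
fit_constrained_gmm <- function(points, intensities, seeds,
                                config = pn_config()$cgmm) {
  X <- as.matrix(points)
  n <- nrow(X)
  K <- length(seeds)
  if (K < 1) stop("need at least one seed")
  eps0 <- config$epsilon0
  eps1 <- (3 * config$neurite_diameter)^3
  lookup <- make_intensity_lookup(X, intensities)

  mu <- X[seeds, , drop = FALSE]
  sigma <- replicate(K, diag(3), simplify = FALSE)
  piw <- rep(1 / K, K)

  pack <- function(sig) {
    info <- lapply(sig, cov_to_prec)
    list(prec = do.call(rbind, lapply(info, function(i) as.numeric(t(i$prec)))),
         logdet = vapply(info, function(i) i$logdet, numeric(1)),
         # spatial truncation radius: 4.5 s.d. (trace bounds the top
         # eigenvalue) plus a margin, so far clusters with negligible
         # responsibility are skipped in the E-step
         reach = vapply(sig, function(s)
           4.5 * sqrt(sum(diag(s))) + 3, numeric(1)))
  }

  rescale_det <- function(s) {
    dt <- det(s)
    if (dt > eps1) {
      fac <- if (isTRUE(config$literal_det_rescale)) eps1 / dt
             else (eps1 / dt)^(1 / 3)
      s <- fac * s
    }
    s
  }

  prev_mu <- NULL
  prev_sigma <- NULL
  prev_ll <- -Inf
  for (iter in seq_len(config$max_iter)) {
    pk <- pack(sigma)
    pass <- cpp_gmm_pass(X, log(piw), mu, pk$prec, pk$logdet, pk$reach)
    # plateau stop: late EM drift moves parameters without improving the
    # likelihood materially; the parameter criterion below still applies
    if (is.finite(prev_ll) &&
        abs(pass$loglik - prev_ll) < 2e-5 * abs(pass$loglik)) break
    prev_ll <- pass$loglik

    keep <- which(pass$Nk > 1e-2)
    if (length(keep) == 0) stop("all mixture components collapsed")
    structure_changed <- length(keep) < length(piw)
    Nk <- pass$Nk[keep]
    Sx <- pass$Sx[keep, , drop = FALSE]
    Sxx <- pass$Sxx[keep, , drop = FALSE]

    piw <- Nk / sum(Nk)
    mu_new <- Sx / Nk
    sigma_new <- lapply(seq_along(keep), function(kk) {
      m <- mu_new[kk, ]
      s <- matrix(c(Sxx[kk, 1], Sxx[kk, 4], Sxx[kk, 5],
                    Sxx[kk, 4], Sxx[kk, 2], Sxx[kk, 6],
                    Sxx[kk, 5], Sxx[kk, 6], Sxx[kk, 3]), 3, 3) / Nk[kk] -
        tcrossprod(m)
      rescale_det((s + t(s)) / 2 + diag(1e-8, 3))
    })

    # intensity constraint: split components centered off the foreground
    out_mu <- list()
    out_sigma <- list()
    out_pi <- numeric(0)
    for (kk in seq_along(keep)) {
      m <- mu_new[kk, ]
      s <- sigma_new[[kk]]
      if (lookup(m) >= eps0) {
        out_mu[[length(out_mu) + 1]] <- m
        out_sigma[[length(out_sigma) + 1]] <- s
        out_pi <- c(out_pi, piw[kk])
      } else {
        eg <- eigen(s, symmetric = TRUE)
        v1 <- eg$vectors[, 1]
        gam <- sqrt(max(eg$values[1], 1e-8))
        bump <- (gam / 2)^2 * tcrossprod(v1)
        for (sgn in c(1, -1)) {
          out_mu[[length(out_mu) + 1]] <- m + sgn * v1 * gam / 2
          out_sigma[[length(out_sigma) + 1]] <- rescale_det(s + bump)
          out_pi <- c(out_pi, piw[kk] / 2)
        }
        structure_changed <- TRUE
      }
    }
    mu <- do.call(rbind, out_mu)
    sigma <- out_sigma
    piw <- out_pi / sum(out_pi)

    if (!structure_changed && !is.null(prev_mu) &&
        nrow(prev_mu) == nrow(mu)) {
      if (param_change(prev_mu, mu, prev_sigma, sigma) < config$stop_tol) break
    }
    prev_mu <- mu
    prev_sigma <- sigma
  }

  # final hard assignment with the converged parameters
  pk <- pack(sigma)
  pass <- cpp_gmm_pass(X, log(piw), mu, pk$prec, pk$logdet, pk$reach)
  assign <- pass$assign

  clusters <- list()
  vox <- round_voxels(X)
  for (k in sort(unique(assign))) {
    members <- which(assign == k)
    # spatial connectivity: points of one columnar region must be 26-connected
    labs <- cpp_label_components26(vox[members, , drop = FALSE])
    for (cc in sort(unique(labs))) {
      sub <- members[labs == cc]
      clusters <- c(clusters, enforce_center_intensity(X, sub, lookup, eps0))
    }
  }

  total <- sum(vapply(clusters, function(cl) length(cl$members), numeric(1)))
  lapply(clusters, function(cl) {
    cl$pi <- length(cl$members) / total
    cl$sigma <- rescale_det(cl$sigma)
    cl
  })
}

# max over clusters of the relative-change L2 norm of (mu, sigma);
# elements with magnitude < 1e-8 are compared absolutely
param_change <- function(mu0, mu1, sig0, sig1) {
  per_cluster <- vapply(seq_len(nrow(mu0)), function(k) {
    old <- c(mu0[k, ], as.numeric(sig0[[k]]))
    new <- c(mu1[k, ], as.numeric(sig1[[k]]))
    rel <- ifelse(abs(old) >= 1e-8, (new - old) / old, new - old)
    sqrt(sum(rel^2))
  }, numeric(1))
  max(per_cluster)
}

# Recursively split a member set along its principal axis until its centroid
# rounds onto a foreground voxel (a singleton always does).
enforce_center_intensity <- function(X, members, lookup, eps0, depth = 0) {
  pts <- X[members, , drop = FALSE]
  mu <- colMeans(pts)
  sig <- empirical_cov(pts)
  if (length(members) == 1 || depth >= 24 || lookup(mu) >= eps0) {
    return(list(list(members = members, pi = NA_real_, mu = mu, sigma = sig)))
  }
  v1 <- eigen(sig, symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(sweep(pts, 2, mu) %*% v1)
  side <- proj >= stats::median(proj)
  if (all(side) || !any(side)) side <- seq_along(proj) <= length(proj) / 2
  c(enforce_center_intensity(X, members[side], lookup, eps0, depth + 1),
    enforce_center_intensity(X, members[!side], lookup, eps0, depth + 1))
}

empirical_cov <- function(pts) {
  if (nrow(pts) < 2) return(diag(1e-6, 3))
  s <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  (s + t(s)) / 2
}

#' Consolidate collinear clusters into columnar regions
#'
#' EM with densely placed seeds over-segments a tube into short, nearly
#' isotropic sections (sometimes split lengthwise into interleaved strands),
#' which destabilizes the terminal-linking geometry.  This pass merges two
#' clusters when their member sets touch (closest points within
#' `contact_tol`) and the merged set is still a clean column: the rms
#' distance of the merged members from their principal line stays below
#' `max_line_rms` (about one tube radius).  Sections of two parallel
#' neurites (transverse spread at least the centerline separation) and
#' crossing regions (two directions, large line residual) fail the
#' columnarity test and are never merged.  Iterates to a fixed point.
#'
#' @param clusters clusters from [fit_constrained_gmm()].
#' @param points full foreground point matrix.
#' @param contact_tol maximum closest-point separation of mergeable clusters.
#' @param max_line_rms columnarity bound on the merged set (voxels).
#' @return consolidated cluster list.
#' @export
merge_lateral_duplicates <- function(clusters, points, contact_tol = 3,
                                     max_line_rms = 2.2) {
  total <- sum(vapply(clusters, function(cl) length(cl$members), numeric(1)))
  line_rms <- function(pts) {
    ctr <- colMeans(pts)
    cen <- sweep(pts, 2, ctr)
    u <- svd(cen, nu = 0)$v[, 1]
    resid <- cen - outer(as.numeric(cen %*% u), u)
    sqrt(mean(rowSums(resid^2)))
  }
  repeat {
    K <- length(clusters)
    if (K < 2) break
    mus <- t(vapply(clusters, function(cl) cl$mu, numeric(3)))
    exts <- vapply(clusters, function(cl) {
      pts <- points[cl$members, , drop = FALSE]
      if (nrow(pts) < 2) return(1)
      2 * sqrt(max(eigen(empirical_cov(pts), symmetric = TRUE,
                         only.values = TRUE)$values))
    }, numeric(1))
    merged_any <- FALSE
    # union-find over clusters; groups carry their accumulated member sets so
    # every candidate merge is tested on the FULL union (this blocks transitive
    # chains through a mixed crossing cluster: once a group is non-columnar,
    # nothing else can join it, and it itself cannot form)
    parent <- seq_len(K)
    gmembers <- lapply(clusters, function(cl) cl$members)
    find <- function(a) {
      while (parent[a] != a) a <- parent[a]
      a
    }
    pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
    pd <- sqrt(rowSums((mus[pairs[, 1], , drop = FALSE] -
                          mus[pairs[, 2], , drop = FALSE])^2))
    keep <- pd <= exts[pairs[, 1]] + exts[pairs[, 2]] + 6
    pairs <- pairs[keep, , drop = FALSE]
    ord <- order(pd[keep])
    for (p in ord) {
      i <- find(pairs[p, 1]); j <- find(pairs[p, 2])
      if (i == j) next
      pi_ <- points[gmembers[[i]], , drop = FALSE]
      pj <- points[gmembers[[j]], , drop = FALSE]
      small <- if (nrow(pi_) <= nrow(pj)) pi_ else pj
      big <- if (nrow(pi_) <= nrow(pj)) pj else pi_
      gap <- suppressWarnings(min(cpp_nn_within(small, big,
                                                contact_tol + 1e-9)$dist))
      if (!is.finite(gap)) next
      both <- rbind(pi_, pj)
      if (line_rms(both) > max_line_rms) next
      parent[j] <- i
      gmembers[[i]] <- c(gmembers[[i]], gmembers[[j]])
      merged_any <- TRUE
    }
    if (!merged_any) break
    roots <- vapply(seq_len(K), find, numeric(1))
    clusters <- lapply(unique(roots), function(r) {
      members <- sort(gmembers[[r]])
      pts <- points[members, , drop = FALSE]
      list(members = members, pi = length(members) / total,
           mu = colMeans(pts), sigma = empirical_cov(pts))
    })
  }
  clusters
}

#' Summarize clusters as a data frame
#'
#' @param clusters result of [fit_constrained_gmm()].
#' @return data frame with one row per cluster (weight, mean, covariance
#'   entries, member count).
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, pi = cl$pi,
               mu_x = cl$mu[1], mu_y = cl$mu[2], mu_z = cl$mu[3],
               s_xx = cl$sigma[1, 1], s_yy = cl$sigma[2, 2],
               s_zz = cl$sigma[3, 3], s_xy = cl$sigma[1, 2],
               s_xz = cl$sigma[1, 3], s_yz = cl$sigma[2, 3],
               n = length(cl$members))
  }))
}
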