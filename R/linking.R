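#' Linking cost between two ellipsoid terminals
#'
#' The cost of joining endpoint `i0` of ellipsoid `ei` to endpoint `j0` of
#' ellipsoid `ej` is the Euclidean terminal gap divided by
#' `(0.5 * (theta/3 + 1.001))^4`, where `theta` in `[-3, 3]` combines three
#' direction cosines: how well each ellipsoid points at the other's terminal
#' (rewarded) and how aligned the two ellipsoid axes are (anti-aligned
#' end-to-end geometry rewarded, so collinear continuation costs about the
#' plain gap and opposing geometry is prohibitive).  Terminals of the same
#' ellipsoid cost `auxiliary_cost`.
#'
#' @param ei,ej `ellipsoid` objects.
#' @param i0,j0 endpoint selectors (0 or 1).
#' @param same_cluster `TRUE` when `ei` and `ej` are the same ellipsoid.
#' @param auxiliary_cost dummy cost (100), also the link rejection threshold.
#' @return scalar cost.
#' @export
pairwise_cost <- function(ei, i0, ej, j0, same_cluster = FALSE,
                          auxiliary_cost = 100) {
  if (same_cluster) return(auxiliary_cost)
  ti <- terminal_of(ei, i0)
  tj <- terminal_of(ej, j0)
  di_own <- term_dir(ei, i0)           # c_i -> t_i,i0
  dj_own <- term_dir(ej, j0)           # c_j -> t_j,j0
  di_x <- unitize(tj - ei$center) %||% di_own   # c_i -> t_j,j0
  dj_x <- unitize(ti - ej$center) %||% dj_own   # c_j -> t_i,i0
  theta <- sum(di_own * di_x) + sum(dj_own * dj_x) - sum(di_own * dj_own)
  gap <- vnorm(ti - tj)
  gap / (0.5 * (theta / 3 + 1.001))^4
}

terminal_of <- function(e, k) if (k == 0) e$t0 else e$t1

# direction from the center to a terminal; degenerate (coincident) terminals
# fall back to the shape's principal axis
term_dir <- function(e, k) {
  v <- unitize(terminal_of(e, k) - e$center)
  if (!is.null(v)) return(v)
  ax <- unitize(e$t1 - e$t0)
  if (!is.null(ax)) return(if (k == 0) -ax else ax)
  c(1, 0, 0)
}

#' Build the 0-1 assignment cost matrix over ellipsoid terminals
#'
#' For `n` ellipsoids the matrix is `4n x 4n`: the top-left `2n x 2n` block
#' holds real terminal-pair costs (terminals ordered `(1,0), (1,1), (2,0),
#' ...`), and the remaining auxiliary blocks are constant `auxiliary_cost`,
#' which lets every terminal opt out of linking.
#'
#' @param ellipsoids list of `ellipsoid` objects.
#' @param auxiliary_cost dummy value (100).
#' @return a `4n x 4n` numeric matrix.
#' @export
build_cost_matrix <- function(ellipsoids, auxiliary_cost = 100) {
  n <- length(ellipsoids)
  if (n < 1) stop("need at least one ellipsoid")
  C <- matrix(auxiliary_cost, 4 * n, 4 * n)
  C[seq_len(2 * n), seq_len(2 * n)] <-
    terminal_cost_block(ellipsoids, auxiliary_cost)
  C
}

# Vectorized real block (2n x 2n) of terminal-pair costs; same-cluster
# entries at the auxiliary value.  Entry-wise identical to pairwise_cost().
terminal_cost_block <- function(ellipsoids, auxiliary_cost = 100) {
  n <- length(ellipsoids)
  Tm <- do.call(rbind, lapply(ellipsoids, function(e) rbind(e$t0, e$t1)))
  Cm <- do.call(rbind, lapply(ellipsoids, function(e) {
    rbind(e$center, e$center)
  }))
  Dm <- do.call(rbind, lapply(ellipsoids, function(e) {
    rbind(term_dir(e, 0), term_dir(e, 1))
  }))
  tt <- rowSums(Tm^2)
  cc <- rowSums(Cm^2)
  # gap between terminals
  g2 <- outer(tt, tt, "+") - 2 * tcrossprod(Tm)
  gap <- sqrt(pmax(g2, 0))
  # cross distances ||t_j - c_i||
  x2 <- outer(cc, tt, "+") - 2 * tcrossprod(Cm, Tm)
  xnorm <- pmax(sqrt(pmax(x2, 0)), 1e-9)
  # <d_i, t_j - c_i> / ||t_j - c_i||
  num1 <- tcrossprod(Dm, Tm) - rowSums(Dm * Cm)
  term1 <- num1 / xnorm
  term3 <- tcrossprod(Dm)
  theta <- term1 + t(term1) - term3
  C <- gap / (0.5 * (theta / 3 + 1.001))^4
  same <- rep(seq_len(n), each = 2)
  C[outer(same, same, "==")] <- auxiliary_cost
  C
}

#' Link ellipsoids and extract the skeleton graph
#'
#' Convenience wrapper: builds the terminal cost block, solves the assignment
#' and returns the skeleton graph.  Because the auxiliary blocks of the full
#' `4n x 4n` matrix are constant, the optimum is attained by solving the
#' `2n x 2n` real block clamped at the auxiliary value (every opted-out
#' terminal costs exactly the auxiliary value either way), which this wrapper
#' does; the accepted link set is identical.
#'
#' @param ellipsoids list of `ellipsoid` objects.
#' @param auxiliary_cost dummy value / rejection threshold (100).
#' @param spacing skeleton resampling step (voxels).
#' @param repair_cost acceptance threshold for the orphan-repair rounds.
#' @param points optional foreground point matrix for member-centroid
#'   centerlines (see [connect_and_skeletonize()]).
#' @return a `skeleton_graph`.
#' @export
link_ellipsoids <- function(ellipsoids, auxiliary_cost = 100, spacing = 1,
                            repair_cost = 20, points = NULL,
                            support_radius = 2.5) {
  R <- pmin(terminal_cost_block(ellipsoids, auxiliary_cost), auxiliary_cost)
  n <- length(ellipsoids)
  term_pos <- do.call(rbind, lapply(ellipsoids, function(e) {
    rbind(e$t0, e$t1)
  }))
  supported <- function(a, b) {
    if (is.null(points)) return(TRUE)
    pa <- term_pos[a, ]
    pb <- term_pos[b, ]
    d <- vnorm(pb - pa)
    if (d <= 3) return(TRUE)
    t <- seq(0, 1, length.out = ceiling(d) + 1)
    samp <- cbind(pa[1] + t * (pb[1] - pa[1]), pa[2] + t * (pb[2] - pa[2]),
                  pa[3] + t * (pb[3] - pa[3]))
    all(is.finite(cpp_nn_within(samp, points, support_radius + 1e-9)$dist))
  }
  all_links <- matrix(integer(0), ncol = 2)
  active <- seq_len(2 * n)
  Rwork <- R
  threshold <- auxiliary_cost
  repeat {
    if (length(active) < 2) break
    sub <- Rwork[active, active, drop = FALSE]
    cand <- assignment_links_general(solve_assignment(sub), sub, active,
                                     threshold)
    if (nrow(cand) == 0) {
      # after the first pass, repair rounds re-run the assignment over
      # orphaned terminals (ties in the symmetric costs can collapse
      # asymmetric assignment cycles), accepting only short-range links
      if (threshold > repair_cost) {
        threshold <- repair_cost
        next
      }
      break
    }
    ok <- vapply(seq_len(nrow(cand)), function(k) {
      supported(cand[k, 1], cand[k, 2])
    }, logical(1))
    # a link across empty space (no foreground under the bridge) is
    # rejected and never reconsidered
    for (k in which(!ok)) {
      Rwork[cand[k, 1], cand[k, 2]] <- auxiliary_cost
      Rwork[cand[k, 2], cand[k, 1]] <- auxiliary_cost
    }
    if (any(ok)) {
      all_links <- rbind(all_links, cand[ok, , drop = FALSE])
      active <- setdiff(active, as.integer(cand[ok, , drop = FALSE]))
    }
  }
  connect_and_skeletonize(ellipsoids, NULL, R, auxiliary_cost, spacing,
                          links = all_links, points = points)
}

# assignment over a subset of terminals (global ids in `ids`)
assignment_links_general <- function(assignment, cost, ids, auxiliary_cost) {
  cand <- list()
  for (r in seq_along(ids)) {
    s <- assignment[r]
    gr <- ids[r]
    gs <- ids[s]
    if (gs == gr) next
    if ((gr - 1) %/% 2 == (gs - 1) %/% 2) next
    if (cost[r, s] >= auxiliary_cost) next
    key <- c(min(gr, gs), max(gr, gs))
    cand[[paste(key, collapse = "-")]] <- c(key, cost[r, s])
  }
  if (length(cand) == 0) return(matrix(integer(0), ncol = 2))
  cand <- do.call(rbind, unname(cand))
  cand <- cand[order(cand[, 3], cand[, 1]), , drop = FALSE]
  used <- logical(0)
  keep <- logical(nrow(cand))
  taken <- integer(0)
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]
    b <- cand[k, 2]
    if (!(a %in% taken) && !(b %in% taken)) {
      keep[k] <- TRUE
      taken <- c(taken, a, b)
    }
  }
  matrix(as.integer(cand[keep, 1:2, drop = FALSE]), ncol = 2)
}

#' Solve a 0-1 assignment problem exactly
#'
#' Minimizes the total cost of a permutation assignment (each row to exactly
#' one column) with a Jonker-Volgenant shortest-augmenting-path solver.
#' Ties are broken deterministically toward lower column indices.
#'
#' @param cost square, finite, nonnegative cost matrix.
#' @return integer vector: `result[r]` is the column assigned to row `r`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be square")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  if (any(cost < 0)) stop("cost matrix must be nonnegative")
  cpp_lap_solve(cost)
}

# Accepted links: real-block pairs of distinct ellipsoids with cost below the
# auxiliary threshold.  Mirror duplicates are collapsed, and when the
# (symmetric-cost) permutation contains asymmetric cycles the candidates are
# filtered greedily by cost so that no terminal joins more than one link.
assignment_links <- function(assignment, cost, n, auxiliary_cost = 100) {
  cand <- list()
  for (r in seq_len(2 * n)) {
    s <- assignment[r]
    if (s > 2 * n || s == r) next
    i <- (r - 1) %/% 2 + 1
    j <- (s - 1) %/% 2 + 1
    if (i == j) next
    if (cost[r, s] >= auxiliary_cost) next
    key <- c(min(r, s), max(r, s))
    cand[[paste(key, collapse = "-")]] <- c(key, cost[r, s])
  }
  if (length(cand) == 0) return(matrix(integer(0), ncol = 2))
  cand <- do.call(rbind, unname(cand))
  cand <- cand[order(cand[, 3], cand[, 1]), , drop = FALSE]
  used <- logical(2 * n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]
    b <- cand[k, 2]
    if (!used[a] && !used[b]) {
      keep[k] <- TRUE
      used[a] <- TRUE
      used[b] <- TRUE
    }
  }
  matrix(as.integer(cand[keep, 1:2, drop = FALSE]), ncol = 2)
}

#' Connect linked ellipsoids and extract the skeleton graph
#'
#' Each ellipsoid contributes a centerline polyline resampled at about
#' 1-voxel spacing; accepted assignment links join the corresponding terminal
#' nodes.  The result is an undirected skeleton graph whose connected
#' components are individual neurite shapes.
#'
#' When `points` is supplied and the ellipsoids carry their member indices,
#' the centerline is grown through the member points: members are sliced into
#' slabs along the ellipsoid's long axis and each slab contributes its
#' centroid, which keeps skeleton nodes on the tube center.  (The raw
#' `t0 - center - t1` axis is used otherwise; its endpoints are extreme
#' member points and can sit on the tube rim, folding the skeleton at links.)
#'
#' @param ellipsoids list of `ellipsoid` objects.
#' @param assignment solved assignment over the [build_cost_matrix()] matrix
#'   (ignored when `links` is given).
#' @param cost the cost matrix (for link acceptance).
#' @param auxiliary_cost link rejection threshold (100).
#' @param spacing resampling step in voxels.
#' @param links optional precomputed 2-column matrix of linked terminal ids.
#' @param points optional full foreground point matrix (enables the
#'   member-centroid centerline).
#' @return a `skeleton_graph`: list with `nodes` (n x 3), `edges` (2-column
#'   index matrix) and `cluster` (per-node ellipsoid index).
#' @export
connect_and_skeletonize <- function(ellipsoids, assignment, cost,
                                    auxiliary_cost = 100, spacing = 1,
                                    links = NULL, points = NULL) {
  n <- length(ellipsoids)
  nodes <- list()
  edges <- list()
  cluster <- list()
  first_node <- integer(n)
  last_node <- integer(n)
  offset <- 0L
  for (i in seq_len(n)) {
    e <- ellipsoids[[i]]
    pl <- ellipsoid_centerline(e, points, spacing)
    k <- nrow(pl)
    nodes[[i]] <- pl
    cluster[[i]] <- rep(i, k)
    if (k > 1) edges[[length(edges) + 1]] <- cbind(offset + seq_len(k - 1),
                                                   offset + seq_len(k - 1) + 1)
    first_node[i] <- offset + 1L
    last_node[i] <- offset + k
    offset <- offset + k
  }
  if (is.null(links)) {
    links <- assignment_links(assignment, cost, n, auxiliary_cost)
  }
  if (nrow(links) > 0) {
    term_node <- function(t) {
      i <- (t - 1) %/% 2 + 1
      if ((t - 1) %% 2 == 0) first_node[i] else last_node[i]
    }
    edges[[length(edges) + 1]] <- cbind(vapply(links[, 1], term_node, numeric(1)),
                                        vapply(links[, 2], term_node, numeric(1)))
  }
  skeleton_graph(do.call(rbind, nodes),
                 if (length(edges)) do.call(rbind, edges)
                 else matrix(integer(0), ncol = 2),
                 unlist(cluster))
}

# Centerline polyline of one ellipsoid, ordered from the t0 side to the t1
# side: slab centroids of the member points along the long axis (tube-center
# nodes), falling back to the raw t0-c-t1 axis without member information.
ellipsoid_centerline <- function(e, points = NULL, spacing = 1,
                                 slab_width = 2) {
  if (is.null(points) || is.null(e$members) || length(e$members) == 0) {
    return(resample_polyline(rbind(e$t0, e$center, e$t1), spacing))
  }
  pts <- points[e$members, , drop = FALSE]
  u <- unitize(e$t1 - e$t0)
  if (is.null(u) || nrow(pts) < 3) {
    ctr <- colMeans(pts)
    return(matrix(ctr, ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  tau <- as.numeric(pts %*% u)
  rng <- range(tau)
  nslab <- max(1L, ceiling((rng[2] - rng[1]) / slab_width))
  cuts <- seq(rng[1], rng[2], length.out = nslab + 1)
  bin <- pmin(pmax(findInterval(tau, cuts, rightmost.closed = TRUE), 1L),
              nslab)
  ctr <- vapply(seq_len(nslab), function(b) {
    if (!any(bin == b)) return(rep(NA_real_, 3))
    colMeans(pts[bin == b, , drop = FALSE])
  }, numeric(3))
  pl <- t(ctr[, !is.na(ctr[1, ]), drop = FALSE])
  if (nrow(pl) < 1) pl <- matrix(colMeans(pts), ncol = 3)
  resample_polyline(pl, spacing)
}

skeleton_graph <- function(nodes, edges, cluster = NULL) {
  structure(list(nodes = nodes, edges = edges, cluster = cluster),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph: %d nodes, %d edges, %d components>\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(skeleton_components(x)))))
  invisible(x)
}

#' Connected-component labels of a skeleton graph
#'
#' @param skel a `skeleton_graph`.
#' @return integer component label per node.
#' @export
skeleton_components <- function(skel) {
  n <- nrow(skel$nodes)
  if (nrow(skel$edges) == 0) return(seq_len(n))
  g <- igraph::graph_from_edgelist(matrix(as.integer(skel$edges), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}
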