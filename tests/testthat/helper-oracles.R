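# Independent reference implementations used as oracles.

# Khachiyan's barycentric-coordinate-descent MVCE (lifted formulation).
# Returns center c and shape Q with (x - c)' Q (x - c) <= 1 for all points.
khachiyan_mvce <- function(pts, tol = 1e-9, max_iter = 100000) {
  pts <- as.matrix(pts)
  m <- nrow(pts)
  d <- ncol(pts)
  Qt <- t(cbind(pts, 1))                      # (d+1) x m lifted points
  u <- rep(1 / m, m)
  for (it in seq_len(max_iter)) {
    Xu <- Qt %*% (u * t(Qt))
    Mi <- colSums(Qt * solve(Xu, Qt))
    j <- which.max(Mi)
    maxM <- Mi[j]
    step <- (maxM - d - 1) / ((d + 1) * (maxM - 1))
    if (maxM - d - 1 < tol * (d + 1)) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- as.numeric(t(pts) %*% u)
  S <- t(pts) %*% (u * pts) - tcrossprod(ctr)
  Q <- solve(S) / d
  list(center = ctr, Q = (Q + t(Q)) / 2)
}

ellipsoid_volume <- function(Q) {
  (4 / 3) * pi / sqrt(det(Q))
}

# Exact minimum assignment cost by bitmask dynamic programming (n <= ~14).
lap_min_cost <- function(C) {
  n <- nrow(C)
  full <- bitwShiftL(1L, n)
  dp <- rep(Inf, full)
  dp[1] <- 0
  pc <- vapply(0:(full - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0), numeric(1))
  for (mask in 0:(full - 2)) {
    if (!is.finite(dp[mask + 1])) next
    i <- pc[mask + 1] + 1          # next unassigned row (1-based)
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1)
      if (bitwAnd(mask, bit) > 0) next
      nxt <- bitwOr(mask, bit)
      v <- dp[mask + 1] + C[i, j]
      if (v < dp[nxt + 1]) dp[nxt + 1] <- v
    }
  }
  dp[full]
}

# Exhaustive information-flow minimum over roots, window = 1, computed
# directly from the definition: for every non-root node with >= 2 neighbors,
# add the minimum over non-parent neighbors of the cosine of the vertex angle
# between the raw segments toward the parent and toward that neighbor.
oracle_flow_for_root <- function(pos, adj, root) {
  n <- nrow(pos)
  parent <- integer(n)
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  total <- 0
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <- TRUE
      parent[v] <- u
      queue <- c(queue, v)
    }
  }
  for (v in seq_len(n)) {
    if (v == root || length(adj[[v]]) < 2) next
    dp <- pos[parent[v], ] - pos[v, ]
    dp <- dp / sqrt(sum(dp^2))
    others <- setdiff(adj[[v]], parent[v])
    total <- total + min(vapply(others, function(c) {
      dc <- pos[c, ] - pos[v, ]
      sum(dp * dc / sqrt(sum(dc^2)))
    }, numeric(1)))
  }
  total
}

oracle_min_flow <- function(pos, edges) {
  adj <- lapply(seq_len(nrow(pos)), function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  })
  min(vapply(seq_len(nrow(pos)), function(r) {
    oracle_flow_for_root(pos, adj, r)
  }, numeric(1)))
}

# Random tree on n nodes: node i > 1 attaches to a random earlier node.
random_tree <- function(n, scale = 10) {
  pos <- matrix(stats::runif(3 * n, 0, scale), ncol = 3)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  head <- integer(n)
  head[edges[, 1]] <- edges[, 2]
  left <- right <- integer(n)
  for (i in seq_len(n)) {
    h <- head[i]
    if (h == 0) next
    if (left[h] == 0) left[h] <- i else if (right[h] == 0) right[h] <- i
    # degree > 3 nodes possible in random trees; extra children are dropped
    # by this naive constructor, so reject such trees in the caller
  }
  list(pos = pos, edges = edges,
       tree = neurite_tree(pos, head, left, right))
}

# random tree whose nodes all have <= 3 tree-neighbors (valid binary forest)
random_binary_tree <- function(n, scale = 10) {
  repeat {
    rt <- random_tree(n, scale)
    deg <- tabulate(rt$edges, nbins = n)
    # node 1 is the constructed root: it can host at most 2 children, other
    # nodes at most 2 children + head
    if (max(deg) <= 3 && deg[1] <= 2) return(rt)
  }
}
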