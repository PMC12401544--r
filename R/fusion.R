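#' Extract boundary terminal nodes near a shared block face
#'
#' Terminal (degree-1) skeleton nodes within `margin` of the face plane are
#' candidate fusion points; each carries a local direction from a
#' least-squares line fit through up to `fit_window` nodes walked along its
#' own branch.
#'
#' @param trees list of `neurite_tree`s in the global frame.
#' @param face list with `axis` (1 = x, 2 = y, 3 = z) and `coord` (the plane
#'   position in global voxel units).
#' @param margin maximum node distance to the face (voxels).
#' @param fit_window nodes used in the line fit.
#' @return data frame with tree id, node id, position and unit direction.
#' @export
extract_boundary_nodes <- function(trees, face, margin = 5, fit_window = 10) {
  rows <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    n <- nrow(tr$pos)
    adj <- edges_to_adj(n, tree_edges(tr))
    deg <- lengths(adj)
    terminals <- which(deg <= 1)
    for (nd in terminals) {
      if (abs(tr$pos[nd, face$axis] - face$coord) > margin) next
      dir <- branch_direction(tr$pos, adj, nd, fit_window)
      rows[[length(rows) + 1]] <- data.frame(
        tree = ti, node = nd,
        x = tr$pos[nd, 1], y = tr$pos[nd, 2], z = tr$pos[nd, 3],
        dx = dir[1], dy = dir[2], dz = dir[3])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tree = integer(), node = integer(), x = numeric(),
                      y = numeric(), z = numeric(), dx = numeric(),
                      dy = numeric(), dz = numeric()))
  }
  do.call(rbind, rows)
}

# PCA line fit through the nodes walked from a terminal along its branch.
branch_direction <- function(pos, adj, start, fit_window) {
  chain <- start
  prev <- 0L
  cur <- start
  while (length(chain) < fit_window) {
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) break
    nxt <- nxt[1]
    prev <- cur
    cur <- nxt
    chain <- c(chain, cur)
  }
  if (length(chain) < 2) return(c(1, 0, 0))
  if (length(chain) == 2) {
    return(unitize(pos[chain[2], ] - pos[chain[1], ]) %||% c(1, 0, 0))
  }
  sub <- pos[chain, , drop = FALSE]
  v <- svd(sweep(sub, 2, colMeans(sub)))$v[, 1]
  unitize(v) %||% c(1, 0, 0)
}

#' Fuse the reconstructions of two adjacent blocks
#'
#' Builds the boundary cost matrix `c(p, q) = d(p, q) * (2 - |cos|)` over the
#' boundary terminals of the two sides (auxiliary blocks at 20, which is also
#' the acceptance threshold), solves the 0-1 assignment exactly, joins
#' accepted pairs node-to-node, and (when `mift = TRUE`) re-minimizes the
#' merged trees and re-runs root-proximity merging at `merge_radius`.
#'
#' @param trees_p,trees_q per-block tree lists (global frame).
#' @param face shared face, as in [extract_boundary_nodes()].
#' @param config the `fusion` section of [pn_config()].
#' @param merge_radius MIFT merge radius for this fusion level (8, 12, 16).
#' @param mift run the information-flow revision after joining.
#' @param window direction-averaging window for the revision.
#' @return list of merged `neurite_tree`s.
#' @export
fuse_adjacent_blocks <- function(trees_p, trees_q, face,
                                 config = pn_config()$fusion,
                                 merge_radius = 8, mift = TRUE, window = 5) {
  bp <- extract_boundary_nodes(trees_p, face, config$margin, config$fit_window)
  bq <- extract_boundary_nodes(trees_q, face, config$margin, config$fit_window)
  trees <- c(trees_p, trees_q)
  q_off <- length(trees_p)
  m <- nrow(bp)
  n <- nrow(bq)
  joins <- NULL
  if (m > 0 && n > 0) {
    aux <- config$auxiliary_cost
    C <- matrix(aux, m + n, m + n)
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        d <- vnorm(c(bp$x[i] - bq$x[j], bp$y[i] - bq$y[j], bp$z[i] - bq$z[j]))
        cosv <- abs(sum(c(bp$dx[i], bp$dy[i], bp$dz[i]) *
                        c(bq$dx[j], bq$dy[j], bq$dz[j])))
        C[i, j] <- d * (2 - cosv)
      }
    }
    asg <- solve_assignment(C)
    for (i in seq_len(m)) {
      j <- asg[i]
      if (j <= n && C[i, j] < aux) {
        joins <- rbind(joins, c(i, j))
      }
    }
  }
  if (!is.null(joins)) {
    # join node-to-node by merging the two trees' graphs with a bridge edge
    for (k in seq_len(nrow(joins))) {
      i <- joins[k, 1]
      j <- joins[k, 2]
      ta <- bp$tree[i]
      tb <- bq$tree[j] + q_off
      # tree indices may have shifted after earlier joins
      ta <- locate_tree(trees, bp[i, c("x", "y", "z")])
      tb <- locate_tree(trees, bq[j, c("x", "y", "z")])
      if (is.na(ta) || is.na(tb) || ta == tb) next
      A <- trees[[ta]]
      B <- trees[[tb]]
      na <- nrow(A$pos)
      anode <- nearest_node(A$pos, as.numeric(bp[i, c("x", "y", "z")]))
      bnode <- nearest_node(B$pos, as.numeric(bq[j, c("x", "y", "z")]))
      pos <- rbind(A$pos, B$pos)
      edges <- rbind(tree_edges(A), tree_edges(B) + na, c(anode, bnode + na))
      merged <- minimize_graph(pos, edges, window)
      trees[[min(ta, tb)]] <- merged
      trees[[max(ta, tb)]] <- NULL
    }
  }
  if (mift) {
    trees <- lapply(trees, minimize_information_flow, window = window)
    trees <- merge_close_trees(trees, merge_radius, window)
    trees <- do.call(c, lapply(trees, split_sharp_turns,
                               cos_threshold = 0.5, window = window))
  }
  trees
}

locate_tree <- function(trees, xyz) {
  p <- matrix(as.numeric(xyz), ncol = 3)
  for (ti in seq_along(trees)) {
    nn <- cpp_nn_within(p, trees[[ti]]$pos, 0.5)
    if (is.finite(nn$dist[1]) && nn$dist[1] < 1e-6) return(ti)
  }
  NA_integer_
}

nearest_node <- function(pos, xyz) {
  which.min(colSums((t(pos) - xyz)^2))
}

#' Hierarchically fuse a grid of per-block reconstructions
#'
#' Fuses blocks pairwise along x, then y, then z, applying the MIFT revision
#' at merge radii 8, 12, 16 over successive levels (then staying at the
#' largest).
#'
#' @param blocks list of per-block results: each a list with `trees` and
#'   `offset` (block origin, voxels) and `shape` (block extent).
#' @param config full [pn_config()].
#' @param mift enable the MIFT revision during fusion.
#' @return list of `neurite_tree`s for the fused domain.
#' @export
fuse_block_grid <- function(blocks, config = pn_config(), mift = TRUE) {
  radii <- config$fusion$merge_radii
  level <- 1
  for (axis in 1:3) {
    coords <- vapply(blocks, function(b) b$offset[axis], numeric(1))
    if (length(unique(coords)) < 2) next
    radius <- radii[min(level, length(radii))]
    keys <- vapply(blocks, function(b) {
      paste(b$offset[-axis], collapse = ",")
    }, character(1))
    merged <- list()
    for (key in unique(keys)) {
      idx <- which(keys == key)
      idx <- idx[order(vapply(blocks[idx], function(b) b$offset[axis],
                              numeric(1)))]
      cur <- blocks[[idx[1]]]
      for (k in idx[-1]) {
        nxt <- blocks[[k]]
        face <- list(axis = axis, coord = nxt$offset[axis])
        cur$trees <- fuse_adjacent_blocks(cur$trees, nxt$trees, face,
                                          config$fusion, radius, mift,
                                          config$mift$smooth_window)
        cur$shape[axis] <- cur$shape[axis] + nxt$shape[axis]
      }
      merged[[length(merged) + 1]] <- cur
    }
    blocks <- merged
    level <- level + 1
  }
  do.call(c, lapply(blocks, function(b) b$trees))
}
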