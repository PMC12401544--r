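#' Binary neurite tree
#'
#' A skeleton component as a binary tree: every node has at most one `head`
#' (parent), one `left` child (the smooth continuation of the incoming
#' neurite) and one `right` child (a side branch).  Link fields are integer
#' node indices, 0 meaning none.
#'
#' @param pos n x 3 node positions.
#' @param head,left,right integer link vectors (0 = none).
#' @return an object of class `neurite_tree`.
#' @export
neurite_tree <- function(pos, head, left, right) {
  n <- nrow(pos)
  stopifnot(length(head) == n, length(left) == n, length(right) == n)
  kids <- c(left[left > 0], right[right > 0])
  if (anyDuplicated(kids)) stop("a node is claimed as child twice")
  structure(list(pos = pos, head = as.integer(head), left = as.integer(left),
                 right = as.integer(right)), class = "neurite_tree")
}

#' @export
print.neurite_tree <- function(x, ...) {
  cat(sprintf("<neurite_tree: %d nodes, root %s, flow %.3f>\n",
              nrow(x$pos), paste(tree_root(x), collapse = ","),
              information_flow(x)))
  invisible(x)
}

tree_root <- function(tree) which(tree$head == 0L)

tree_edges <- function(tree) {
  i <- which(tree$head > 0L)
  cbind(i, tree$head[i])
}

edges_to_adj <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]
    b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else as.integer(v))
}

# Chord from node i toward neighbor j, walked along the chain through j for
# up to `window` nodes (suppresses 1-voxel jitter): direction, chord length
# and steps walked.  dir is NULL for zero-length chords.
chain_chord <- function(pos, adj, i, j, window) {
  prev <- i
  cur <- j
  steps <- 1
  while (steps < window && length(adj[[cur]]) == 2) {
    nxt <- adj[[cur]][adj[[cur]] != prev]
    if (length(nxt) != 1) break
    prev <- cur
    cur <- nxt
    steps <- steps + 1
  }
  len <- vnorm(pos[cur, ] - pos[i, ])
  v <- unitize(pos[cur, ] - pos[i, ])
  if (is.null(v)) v <- unitize(pos[j, ] - pos[i, ])
  list(dir = v, len = len, steps = steps)
}

chain_dir <- function(pos, adj, i, j, window) {
  chain_chord(pos, adj, i, j, window)$dir
}

# Per-node list of direction matrices toward each neighbor (rows follow
# adj order; NA rows mark zero-length directions).
all_chain_dirs <- function(pos, adj, window) {
  lapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0) return(matrix(numeric(0), ncol = 3))
    t(vapply(nb, function(j) {
      v <- chain_dir(pos, adj, i, j, window)
      if (is.null(v)) rep(NA_real_, 3) else v
    }, numeric(3)))
  })
}

# g(n, p): information-flow contribution of node n when its head is neighbor
# p -- the minimum over the other neighbors c of cos(angle p-n-c).
# Zero-length directions contribute 0.
local_flow <- function(dirs_n, nb, p_idx) {
  k <- length(nb)
  if (k < 2) return(0)
  dp <- dirs_n[p_idx, ]
  vals <- vapply(seq_len(k)[-p_idx], function(ci) {
    dc <- dirs_n[ci, ]
    if (anyNA(dp) || anyNA(dc)) 0 else sum(dp * dc)
  }, numeric(1))
  min(vals)
}

#' Total information flow of a neurite tree
#'
#' Sums, over the nodes that have both a head and a left child, the cosine of
#' the vertex angle between the directions toward the head and toward the
#' left child.  A perfectly smooth chain contributes -1 per interior node;
#' minimizing this total therefore favors smooth neurites.  Directions are
#' averaged over up to `window` nodes along each chain.
#'
#' @param tree a `neurite_tree`.
#' @param window direction-averaging window (nodes); 1 uses raw segments.
#' @return scalar information flow.
#' @export
information_flow <- function(tree, window = 1) {
  n <- nrow(tree$pos)
  if (n == 0) return(0)
  adj <- edges_to_adj(n, tree_edges(tree))
  total <- 0
  for (i in seq_len(n)) {
    h <- tree$head[i]
    l <- tree$left[i]
    if (h == 0 || l == 0) next
    dh <- chain_dir(tree$pos, adj, i, h, window)
    dl <- chain_dir(tree$pos, adj, i, l, window)
    if (is.null(dh) || is.null(dl)) next
    total <- total + sum(dh * dl)
  }
  total
}

#' Minimize the information flow of a tree by exact re-rooting
#'
#' Evaluates the total information flow for every candidate root of the
#' (undirected) tree using O(1) re-rooting transitions, selects the minimizing
#' root (lowest index on ties) and rebuilds the binary structure: at every
#' node the left child is the smoothest continuation of the incoming
#' direction and any other child attaches as the right branch.  This realizes
#' the three local moves of the greedy formulation (keep / exchange children /
#' reverse head) globally, so the result attains the exhaustive minimum over
#' root choices and never increases the flow.
#'
#' @param tree a `neurite_tree`.
#' @param window direction-averaging window (nodes).
#' @return a revised `neurite_tree` (node positions unchanged).
#' @export
minimize_information_flow <- function(tree, window = 1) {
  minimize_graph(tree$pos, tree_edges(tree), window)
}

#' Information flow for every candidate root
#'
#' Returns the total information flow the tree would attain when re-rooted at
#' each node (same quantity [minimize_information_flow()] minimizes), computed
#' with the O(1) re-rooting transitions.
#'
#' @param tree a `neurite_tree`.
#' @param window direction-averaging window (nodes).
#' @return numeric vector, one flow value per node.
#' @export
information_flow_profile <- function(tree, window = 1) {
  pos <- tree$pos
  edges <- tree_edges(tree)
  n <- nrow(pos)
  if (n == 1 || nrow(edges) == 0) return(rep(0, n))
  adj <- edges_to_adj(n, edges)
  dirs <- all_chain_dirs(pos, adj, window)
  graph_flow_profile(pos, adj, dirs)$Froot
}

graph_flow_profile <- function(pos, adj, dirs) {
  n <- nrow(pos)

  # g[n][k]: contribution of node n when its head is its k-th neighbor
  gval <- lapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    vapply(seq_along(nb), function(k) local_flow(dirs[[i]], nb, k),
           numeric(1))
  })
  gof <- function(i, p) {
    k <- match(p, adj[[i]])
    gval[[i]][k]
  }

  # flow with root 1, then reroot transitions over a BFS of the tree
  ord <- integer(n)
  parent <- integer(n)
  ord[1] <- 1L
  seen <- logical(n)
  seen[1] <- TRUE
  qi <- 1L
  qn <- 1L
  while (qi <= qn) {
    u <- ord[qi]
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        qn <- qn + 1L
        ord[qn] <- v
        parent[v] <- u
      }
    }
    qi <- qi + 1L
  }
  if (qn < n) stop("tree graph is not connected")

  Fbase <- 0
  for (v in ord[-1]) Fbase <- Fbase + gof(v, parent[v])
  Froot <- rep(NA_real_, n)
  Froot[1] <- Fbase
  for (v in ord[-1]) {
    u <- parent[v]
    Froot[v] <- Froot[u] + gof(u, v) - gof(v, u)
  }
  list(Froot = Froot)
}

minimize_graph <- function(pos, edges, window) {
  n <- nrow(pos)
  if (n == 1 || nrow(edges) == 0) {
    return(neurite_tree(pos, rep(0L, n), rep(0L, n), rep(0L, n)))
  }
  adj <- edges_to_adj(n, edges)
  dirs <- all_chain_dirs(pos, adj, window)
  Froot <- graph_flow_profile(pos, adj, dirs)$Froot
  root <- which.min(Froot)
  rebuild_binary(pos, adj, root, dirs)
}

# Orient the tree at `root`; left = smoothest continuation child.  A root
# with more than two children receives stacked zero-length duplicates.
rebuild_binary <- function(pos, adj, root, dirs) {
  n <- nrow(pos)
  head <- left <- right <- integer(n)
  parent_of <- integer(n)
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  while (length(queue) > 0) {
    u <- queue[1]
    queue <- queue[-1]
    nb <- adj[[u]]
    ch <- setdiff(nb, if (u == root) integer(0) else parent_of[u])
    ch <- ch[!seen[ch]]
    if (length(ch) > 0) {
      if (u != root && length(ch) >= 2) {
        p_idx <- match(parent_of[u], adj[[u]])
        dp <- dirs[[u]][p_idx, ]
        sc <- vapply(ch, function(c) {
          dc <- dirs[[u]][match(c, adj[[u]]), ]
          if (anyNA(dp) || anyNA(dc)) 0 else sum(dp * dc)
        }, numeric(1))
        ch <- ch[order(sc, ch)]
      }
      extra <- integer(0)
      if (length(ch) > 2) {
        # should only happen at the root; chain extras above it
        extra <- ch[-(1:2)]
        ch <- ch[1:2]
        anchor <- u
        for (c in extra) {
          pos <- rbind(pos, pos[u, , drop = FALSE])
          d <- nrow(pos)
          head <- c(head, 0L)
          left <- c(left, anchor)
          right <- c(right, c)
          head[anchor] <- d
          head[c] <- d
          parent_of <- c(parent_of, u)
          parent_of[c] <- u
          seen <- c(seen, TRUE)
          seen[c] <- TRUE
          queue <- c(queue, c)
          anchor <- d
        }
      }
      left[u] <- ch[1]
      if (length(ch) >= 2) right[u] <- ch[2]
      for (c in ch) {
        head[c] <- u
        parent_of[c] <- u
        seen[c] <- TRUE
        queue <- c(queue, c)
      }
    }
  }
  neurite_tree(pos, head, left, right)
}

#' Topology matrix of a neurite tree
#'
#' K x K matrix with `W[i, j] = -1/-2/-3` when node `i` is the head / left /
#' right of node `j`, 0 otherwise.  A root `r` has `W[r, ]` restricted to
#' `{0, -1}`.
#'
#' @param tree a `neurite_tree`.
#' @return integer matrix.
#' @export
as_topology_matrix <- function(tree) {
  n <- nrow(tree$pos)
  W <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    if (tree$head[j] > 0) W[tree$head[j], j] <- -1L
    if (tree$left[j] > 0) W[tree$left[j], j] <- -2L
    if (tree$right[j] > 0) W[tree$right[j], j] <- -3L
  }
  W
}

#' Split a tree at implausibly sharp turns
#'
#' After minimization, any node whose head-to-left-child vertex angle is
#' sharper than the threshold (local flow contribution `> cos_threshold`,
#' i.e. a direction change of more than 120 degrees at the default 0.5) has
#' its left link cut; both parts are re-minimized.  Neurites rarely turn this
#' sharply, so such links are almost always reconstruction errors.
#'
#' @param tree a `neurite_tree`.
#' @param cos_threshold cut threshold on the cosine contribution.
#' @param window direction-averaging window.
#' @return list of `neurite_tree`s.
#' @export
split_sharp_turns <- function(tree, cos_threshold = 0.5, window = 1) {
  out <- list()
  queue <- list(tree)
  while (length(queue) > 0) {
    tr <- queue[[1]]
    queue <- queue[-1]
    n <- nrow(tr$pos)
    adj <- edges_to_adj(n, tree_edges(tr))
    worst <- -Inf
    worst_node <- 0L
    for (i in seq_len(n)) {
      h <- tr$head[i]
      l <- tr$left[i]
      if (h == 0 || l == 0) next
      dh <- chain_chord(tr$pos, adj, i, h, window)
      dl <- chain_chord(tr$pos, adj, i, l, window)
      if (is.null(dh$dir) || is.null(dl$dir)) next
      # a sustained turn: short folded chords are local jitter (axis
      # overshoot at linked terminals), not a real direction change
      if (window > 1 && (dh$len < 0.6 * dh$steps || dl$len < 0.6 * dl$steps)) next
      v <- sum(dh$dir * dl$dir)
      if (v > worst) {
        worst <- v
        worst_node <- i
      }
    }
    if (worst_node == 0L || worst <= cos_threshold) {
      out[[length(out) + 1]] <- tr
      next
    }
    edges <- tree_edges(tr)
    cut <- c(tr$left[worst_node], worst_node)
    keep <- !(edges[, 1] == cut[1] & edges[, 2] == cut[2]) &
            !(edges[, 1] == cut[2] & edges[, 2] == cut[1])
    parts <- split_graph_components(tr$pos, edges[keep, , drop = FALSE])
    for (p in parts) {
      queue[[length(queue) + 1]] <- minimize_graph(p$pos, p$edges, window)
    }
  }
  out
}

split_graph_components <- function(pos, edges) {
  n <- nrow(pos)
  memb <- if (nrow(edges) == 0) seq_len(n) else {
    g <- igraph::graph_from_edgelist(matrix(as.integer(edges), ncol = 2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    as.integer(igraph::components(g)$membership)
  }
  lapply(sort(unique(memb)), function(cc) {
    idx <- which(memb == cc)
    remap <- match(seq_len(n), idx)
    sub <- edges[edges[, 1] %in% idx & edges[, 2] %in% idx, , drop = FALSE]
    list(pos = pos[idx, , drop = FALSE],
         edges = cbind(remap[sub[, 1]], remap[sub[, 2]]))
  })
}

#' Merge trees whose roots touch another tree's skeleton
#'
#' When a tree's root lies within `merge_radius` of another tree's skeleton,
#' the root is grafted onto the nearest skeleton node (next-nearest if that
#' would create a degree > 3 node), the merged tree is re-minimized, and the
#' scan repeats to a fixed point.  Smaller trees are merged into larger ones
#' first.
#'
#' @param trees list of `neurite_tree`s.
#' @param merge_radius graft radius in voxels (8 within blocks; 8, 12, 16 at
#'   successive fusion levels).
#' @param window direction-averaging window.
#' @return list of `neurite_tree`s.
#' @export
merge_close_trees <- function(trees, merge_radius = 8, window = 1) {
  repeat {
    if (length(trees) < 2) return(trees)
    sizes <- vapply(trees, function(t) nrow(t$pos), numeric(1))
    ord <- order(sizes)  # smallest first: merge small into large
    merged <- FALSE
    for (bi in ord) {
      rootb <- tree_root(trees[[bi]])[1]
      adjb <- edges_to_adj(nrow(trees[[bi]]$pos), tree_edges(trees[[bi]]))
      if (length(adjb[[rootb]]) > 1) next  # only dangling (leaf) roots graft
      rpos <- trees[[bi]]$pos[rootb, , drop = FALSE]
      rdir <- branch_direction(trees[[bi]]$pos, adjb, rootb, 10)
      best <- list(d = Inf, ai = 0L, node = 0L)
      for (ai in seq_along(trees)) {
        if (ai == bi) next
        nn <- cpp_nn_within(rpos, trees[[ai]]$pos, merge_radius)
        if (is.finite(nn$dist[1]) && nn$dist[1] < merge_radius &&
            nn$dist[1] < best$d) {
          # the graft must continue the dangling branch, not step sideways
          # onto a neurite merely passing nearby
          gapv <- trees[[ai]]$pos[nn$index[1], ] - rpos[1, ]
          if (nn$dist[1] > 1.5 &&
              abs(sum(gapv / nn$dist[1] * rdir)) < 0.6) next
          # a bridge longer than a tube radius is only believable between
          # facing chain ends; grafting onto the middle of another tree from
          # that far away would join a neurite merely passing nearby
          if (nn$dist[1] > 3) {
            adjA <- edges_to_adj(nrow(trees[[ai]]$pos),
                                 tree_edges(trees[[ai]]))
            tnode <- nn$index[1]
            if (length(adjA[[tnode]]) > 1) next
            adir <- branch_direction(trees[[ai]]$pos, adjA, tnode, 10)
            if (abs(sum(gapv / nn$dist[1] * adir)) < 0.6) next
          }
          best <- list(d = nn$dist[1], ai = ai, node = nn$index[1])
        }
      }
      if (best$ai > 0L) {
        trees <- graft_trees(trees, best$ai, best$node, bi, rootb,
                             merge_radius, window)
        merged <- TRUE
        break
      }
    }
    if (!merged) return(trees)
  }
}

graft_trees <- function(trees, ai, target, bi, rootb, merge_radius, window) {
  A <- trees[[ai]]
  B <- trees[[bi]]
  # avoid degree > 3 at the graft point: take the next-nearest node if needed
  adjA <- edges_to_adj(nrow(A$pos), tree_edges(A))
  if (length(adjA[[target]]) >= 3) {
    d <- cpp_nn_within(B$pos[rootb, , drop = FALSE], A$pos,
                       merge_radius)  # nearest only; fall back to scan
    dist_all <- sqrt(colSums((t(A$pos) - B$pos[rootb, ])^2))
    cand <- order(dist_all)
    cand <- cand[dist_all[cand] < merge_radius &
                 vapply(cand, function(v) length(adjA[[v]]) < 3, logical(1))]
    if (length(cand) == 0) {
      # nothing graftable; drop this pairing by returning unchanged trees
      return(trees)
    }
    target <- cand[1]
  }
  nA <- nrow(A$pos)
  pos <- rbind(A$pos, B$pos)
  eB <- tree_edges(B) + nA
  edges <- rbind(tree_edges(A), eB, c(rootb + nA, target))
  merged <- minimize_graph(pos, edges, window)
  trees[[min(ai, bi)]] <- merged
  trees[[max(ai, bi)]] <- NULL
  trees
}

#' Heal gaps between facing tree terminals
#'
#' Within one block, fragments of the same neurite can remain separate when
#' neither fragment's root lands at the gap.  This step applies the boundary
#' fusion cost `d * (2 - |cos|)` to pairs of terminal (degree <= 1) nodes of
#' different trees within `radius` of each other, joining the cheapest pair
#' at a time and re-minimizing, until no pair remains.
#'
#' @param trees list of `neurite_tree`s.
#' @param radius maximum terminal-terminal gap (voxels).
#' @param window direction-averaging window for the re-minimization.
#' @param fit_window nodes used for terminal direction fits.
#' @return list of `neurite_tree`s.
#' @export
heal_terminal_gaps <- function(trees, radius = 8, window = 5,
                               fit_window = 8) {
  repeat {
    if (length(trees) < 2) return(trees)
    term <- list()
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]
      adj <- edges_to_adj(nrow(tr$pos), tree_edges(tr))
      for (nd in which(lengths(adj) <= 1)) {
        inward <- if (length(adj[[nd]]) == 1) {
          chain_chord(tr$pos, adj, nd, adj[[nd]][1], fit_window)$dir
        } else NULL
        term[[length(term) + 1]] <- list(
          tree = ti, node = nd, pos = tr$pos[nd, ],
          outward = if (is.null(inward)) NULL else -inward)
      }
    }
    if (length(term) < 2) return(trees)
    # trees that substantially duplicate each other's coverage are debris,
    # not fragments; joining them would fold the skeleton back on itself
    overlap_ok <- function(ti, tj) {
      a <- trees[[ti]]$pos
      b <- trees[[tj]]$pos
      small <- if (nrow(a) <= nrow(b)) a else b
      big <- if (nrow(a) <= nrow(b)) b else a
      mean(cpp_nn_within(small, big, 2.51)$dist <= 2.5) <= 0.5
    }
    best <- NULL
    for (a in seq_along(term)) {
      for (b in seq_along(term)) {
        if (b <= a || term[[a]]$tree == term[[b]]$tree) next
        oa <- term[[a]]$outward
        ob <- term[[b]]$outward
        if (is.null(oa) || is.null(ob)) next
        gapv <- term[[b]]$pos - term[[a]]$pos
        d <- vnorm(gapv)
        if (d >= radius) next
        # the walk must leave A roughly along the gap and enter B against
        # its outward direction (true continuation, never a fold and never
        # a sideways hop across parallel tubes)
        if (d >= 1) {
          u <- gapv / d
          if (sum(u * oa) < 0.5 || sum(u * ob) > -0.5) next
        } else if (sum(oa * ob) > -0.5) next
        if (!overlap_ok(term[[a]]$tree, term[[b]]$tree)) next
        cost <- d * (2 - abs(sum(oa * ob)))
        if (is.null(best) || cost < best$cost) {
          best <- list(a = term[[a]], b = term[[b]], cost = cost)
        }
      }
    }
    if (is.null(best)) return(trees)
    ta <- best$a$tree
    tb <- best$b$tree
    A <- trees[[ta]]
    B <- trees[[tb]]
    pos <- rbind(A$pos, B$pos)
    edges <- rbind(tree_edges(A), tree_edges(B) + nrow(A$pos),
                   c(best$a$node, best$b$node + nrow(A$pos)))
    trees[[min(ta, tb)]] <- minimize_graph(pos, edges, window)
    trees[[max(ta, tb)]] <- NULL
  }
}

#' Trim duplicated coverage from a tree forest
#'
#' Processes trees from largest to smallest: nodes of a smaller tree that lie
#' within `trim_tol` of an already-kept tree duplicate coverage (interleaved
#' strands, crossing debris) and are removed; the remaining pieces are kept
#' when they have at least `min_nodes` nodes and re-minimized.  The
#' complementary fragments this produces are then ready for
#' [heal_terminal_gaps()].
#'
#' @param trees list of `neurite_tree`s.
#' @param trim_tol duplication tolerance (voxels).
#' @param min_nodes minimum surviving piece size.
#' @param window direction-averaging window.
#' @return deduplicated list of `neurite_tree`s.
#' @export
dedupe_forest <- function(trees, trim_tol = 2, min_nodes = 5, window = 5) {
  if (length(trees) < 2) return(trees)
  ord <- order(vapply(trees, function(t) nrow(t$pos), numeric(1)),
               decreasing = TRUE)
  kept_cloud <- NULL
  out <- list()
  for (ti in ord) {
    tr <- trees[[ti]]
    pos <- tr$pos
    red <- if (is.null(kept_cloud)) rep(FALSE, nrow(pos)) else {
      cpp_nn_within(pos, kept_cloud, trim_tol + 1e-9)$dist <= trim_tol
    }
    if (!any(red)) {
      out[[length(out) + 1]] <- tr
      kept_cloud <- rbind(kept_cloud, pos)
      next
    }
    keep <- which(!red)
    if (length(keep) < min_nodes) next
    remap <- match(seq_len(nrow(pos)), keep)
    edges <- tree_edges(tr)
    sub <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    parts <- split_graph_components(pos[keep, , drop = FALSE],
                                    cbind(remap[sub[, 1]], remap[sub[, 2]]))
    for (p in parts) {
      if (nrow(p$pos) < min_nodes) next
      out[[length(out) + 1]] <- minimize_graph(p$pos, p$edges, window)
      kept_cloud <- rbind(kept_cloud, p$pos)
    }
  }
  out
}

#' Drop redundant skeleton debris
#'
#' Linked ellipsoid axes can overshoot at terminals and crossings, leaving
#' small skeleton fragments that duplicate coverage already provided by the
#' main trees (folded end caps, crossing debris).  A fragment of at most
#' `max_nodes` nodes is dropped when at least 90% of its nodes lie within
#' `tol` voxels of the other trees, so the represented geometry is unchanged.
#'
#' @param trees list of `neurite_tree`s.
#' @param tol redundancy tolerance (voxels).
#' @param max_nodes only fragments up to this size are considered debris.
#' @return filtered list of `neurite_tree`s.
#' @export
absorb_redundant_trees <- function(trees, tol = 2, max_nodes = 40) {
  repeat {
    if (length(trees) < 2) return(trees)
    sizes <- vapply(trees, function(t) nrow(t$pos), numeric(1))
    dropped <- FALSE
    for (bi in order(sizes)) {
      if (sizes[bi] > max_nodes) next
      others <- do.call(rbind, lapply(trees[-bi], function(t) t$pos))
      d <- cpp_nn_within(trees[[bi]]$pos, others, tol + 1e-9)$dist
      if (mean(d <= tol) >= 0.9) {
        trees[[bi]] <- NULL
        dropped <- TRUE
        break
      }
    }
    if (!dropped) return(trees)
  }
}

#' Build binary trees from a skeleton graph
#'
#' Per connected component: cycles are broken on a minimum-spanning tree
#' (dropping the longest redundant links), nodes of degree above 3 are split
#' into stacked zero-length duplicates, the head is taken at a far endpoint
#' of the longest path, and the component is oriented so that chains run
#' through left links and side branches attach through right links.
#'
#' @param skel a `skeleton_graph` from [connect_and_skeletonize()].
#' @param window direction-averaging window for child ordering.
#' @return list of `neurite_tree`s.
#' @export
build_binary_trees <- function(skel, window = 1) {
  parts <- split_graph_components(skel$nodes, skel$edges)
  lapply(parts, function(p) {
    n <- nrow(p$pos)
    edges <- p$edges
    if (nrow(edges) >= n) {
      # cycles: keep the shortest spanning structure
      w <- sqrt(rowSums((p$pos[edges[, 1], , drop = FALSE] -
                         p$pos[edges[, 2], , drop = FALSE])^2))
      g <- igraph::graph_from_edgelist(matrix(as.integer(edges), ncol = 2),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
      gm <- igraph::mst(g, weights = w)
      edges <- igraph::as_edgelist(gm)
      storage.mode(edges) <- "integer"
    }
    capped <- cap_degrees(p$pos, edges)
    adj <- edges_to_adj(nrow(capped$pos), capped$edges)
    root <- longest_path_end(capped$pos, adj)
    dirs <- all_chain_dirs(capped$pos, adj, window)
    rebuild_binary(capped$pos, adj, root, dirs)
  })
}

# split nodes of degree > 3 into stacked zero-length duplicates
cap_degrees <- function(pos, edges, maxdeg = 3) {
  repeat {
    adj <- edges_to_adj(nrow(pos), edges)
    deg <- lengths(adj)
    v <- which(deg > maxdeg)
    if (length(v) == 0) return(list(pos = pos, edges = edges))
    v <- v[1]
    nb <- adj[[v]]
    move <- nb[-(seq_len(maxdeg - 1))]   # keep maxdeg-1 neighbors + duplicate
    pos <- rbind(pos, pos[v, , drop = FALSE])
    d <- nrow(pos)
    drop <- (edges[, 1] == v & edges[, 2] %in% move) |
            (edges[, 2] == v & edges[, 1] %in% move)
    edges <- rbind(edges[!drop, , drop = FALSE],
                   cbind(rep(d, length(move)), move),
                   c(v, d))
  }
}

# endpoint of the (edge-length weighted) longest path; lowest index on ties
longest_path_end <- function(pos, adj) {
  n <- nrow(pos)
  if (n == 1) return(1L)
  far <- function(src) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        nd <- dist[u] + vnorm(pos[v, ] - pos[u, ])
        if (nd < dist[v]) {
          dist[v] <- nd
          queue <- c(queue, v)
        }
      }
    }
    dist[!is.finite(dist)] <- -1
    which.max(dist)
  }
  a <- far(1L)
  b <- far(a)
  min(a, b)
}
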