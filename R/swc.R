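#' Read a skeleton from an SWC file
#'
#' SWC is the standard 7-column whitespace format for neuron skeletons:
#' `id type x y z radius parent`, with `parent = -1` marking a root.
#' Comment lines starting with `#` and blank lines are ignored.
#'
#' @param path path to an SWC file.
#' @return a data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`, in file order.
#' @seealso [write_swc()]
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    return(data.frame(id = integer(), type = integer(), x = numeric(),
                      y = numeric(), z = numeric(), radius = numeric(),
                      parent = integer()))
  }
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7 || anyNA(suppressWarnings(as.numeric(f)))) {
      stop("malformed SWC line ", i, ": '", lines[i], "'")
    }
    as.numeric(f)
  })
  m <- do.call(rbind, rows)
  rec <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                    parent = as.integer(m[, 7]))
  validate_swc(rec)
  rec
}

#' Write a skeleton to an SWC file
#'
#' @param records data frame as returned by [read_swc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(records, path) {
  validate_swc(records)
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   records$id, records$type, records$x, records$y,
                   records$z, records$radius, records$parent)
  writeLines(lines, path)
  invisible(path)
}

validate_swc <- function(rec) {
  if (anyDuplicated(rec$id)) stop("SWC ids are not unique")
  dangling <- rec$parent >= 0 & !(rec$parent %in% rec$id)
  if (any(dangling)) {
    stop("SWC parent references missing id(s): ",
         paste(unique(rec$parent[dangling]), collapse = ", "))
  }
  # acyclicity: follow parents; every chain must terminate at a root
  idx <- match(rec$parent, rec$id)
  for (start in seq_len(nrow(rec))) {
    seen <- integer(0)
    i <- start
    while (!is.na(idx[i])) {
      if (i %in% seen) stop("SWC parent relation contains a cycle at id ",
                            rec$id[i])
      seen <- c(seen, i)
      i <- idx[i]
    }
  }
  invisible(rec)
}

# Convert a forest of neurite trees to SWC records (type code 2, axon).
# Input trees come from the MIFT module (see neurite_tree()).
trees_to_swc <- function(trees, radius = 3) {
  recs <- list()
  next_id <- 1L
  for (tr in trees) {
    n <- nrow(tr$pos)
    if (n == 0) next
    ids <- seq.int(next_id, next_id + n - 1L)
    parent <- ifelse(tr$head == 0L, -1L, ids[pmax(tr$head, 1L)])
    recs[[length(recs) + 1]] <- data.frame(
      id = ids, type = 2L, x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3],
      radius = radius, parent = as.integer(parent))
    next_id <- next_id + n
  }
  if (length(recs) == 0) {
    return(data.frame(id = integer(), type = integer(), x = numeric(),
                      y = numeric(), z = numeric(), radius = numeric(),
                      parent = integer()))
  }
  do.call(rbind, recs)
}

# SWC records -> list of neurite trees (one per root-connected component).
swc_to_trees <- function(rec) {
  if (nrow(rec) == 0) return(list())
  idx <- match(rec$parent, rec$id)
  edges <- cbind(which(!is.na(idx)), idx[!is.na(idx)])
  graph_components_to_trees(as.matrix(rec[, c("x", "y", "z")]), edges)
}

# Positions + (child, parent) edges -> one neurite_tree per connected
# component, rooted at the component's recorded root (a node without a
# parent) when one exists.  Nodes with more than two children are handled by
# the binary rebuild (degree is capped first, as in skeleton tree building).
graph_components_to_trees <- function(pos, edges) {
  n <- nrow(pos)
  has_parent <- rep(FALSE, n)
  if (nrow(edges) > 0) has_parent[edges[, 1]] <- TRUE
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
    sube <- cbind(remap[sub[, 1]], remap[sub[, 2]])
    posi <- pos[idx, , drop = FALSE]
    if (nrow(sube) == 0) {
      return(neurite_tree(posi, rep(0L, length(idx)), rep(0L, length(idx)),
                          rep(0L, length(idx))))
    }
    capped <- cap_degrees(posi, sube)
    adj <- edges_to_adj(nrow(capped$pos), capped$edges)
    root <- which(!has_parent[idx])
    root <- if (length(root) > 0) root[1] else 1L
    rebuild_binary(capped$pos, adj, root,
                   all_chain_dirs(capped$pos, adj, 1))
  })
}
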