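#' Reconstruct neurites from a distance-field (or segmentation) volume
#'
#' Runs the full per-block pipeline: foreground extraction, density-guided
#' seed selection, constrained Gaussian mixture clustering into columnar
#' regions, minimum-volume covering ellipsoid characterization, 0-1 assignment
#' linking, and (optionally) the minimal information flow tree revision
#' (re-rooting, root-proximity merging at the block-level radius, and
#' sharp-turn splitting, iterated to a fixed point).
#'
#' @param field a [voxel_volume()] holding the distance field in `[0, 1]`
#'   (or an 8-bit segmentation).
#' @param config a [pn_config()] list.
#' @param revise run the information-flow revision.
#' @return a `pn_reconstruction`: list with `trees`, `clusters`, `ellipsoids`,
#'   `skeleton`, `offset` and `shape`.
#' @export
reconstruct <- function(field, config = pn_config(), revise = TRUE) {
  fg <- extract_foreground_points(field, config$foreground$threshold)
  shape <- rev(dim(field$data))
  if (nrow(fg$points) == 0) {
    return(structure(list(trees = list(), clusters = list(),
                          ellipsoids = list(),
                          skeleton = skeleton_graph(matrix(numeric(0), ncol = 3),
                                                    matrix(integer(0), ncol = 2)),
                          offset = field$offset, shape = shape),
                     class = "pn_reconstruction"))
  }
  dens <- compute_density(fg$points, config$cgmm$density_cutoff_radius)
  sel <- select_seeds(fg$points, dens, config$cgmm$seed_exclusion_radius)
  clusters <- fit_constrained_gmm(fg$points, fg$intensity, sel$seeds,
                                  config$cgmm)
  clusters <- merge_lateral_duplicates(clusters, fg$points)
  ellipsoids <- list()
  for (i in seq_along(clusters)) {
    ellipsoids <- c(ellipsoids,
                    characterize_cluster(clusters[[i]], fg$points,
                                         config$mvce, cluster_id = i))
  }
  skel <- link_ellipsoids(ellipsoids, config$linking$auxiliary_cost,
                          config$linking$resample_spacing,
                          config$linking$repair_cost, points = fg$points)
  trees <- build_binary_trees(skel, config$mift$smooth_window)
  if (revise) trees <- revise_trees(trees, config$mift)
  structure(list(trees = trees, clusters = clusters,
                 ellipsoids = ellipsoids, skeleton = skel,
                 offset = field$offset, shape = shape),
            class = "pn_reconstruction")
}

#' @export
print.pn_reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction: %d clusters, %d ellipsoids, %d trees>\n",
              length(x$clusters), length(x$ellipsoids), length(x$trees)))
  invisible(x)
}

#' Information-flow revision of a tree forest
#'
#' Minimizes each tree's information flow, merges trees whose roots touch
#' another tree's skeleton, and splits implausibly sharp turns, iterating the
#' merge/split cycle to a fixed point (bounded rounds).
#'
#' @param trees list of `neurite_tree`s.
#' @param mift_config the `mift` section of [pn_config()].
#' @return revised list of `neurite_tree`s.
#' @export
revise_trees <- function(trees, mift_config = pn_config()$mift) {
  w <- mift_config$smooth_window
  trees <- lapply(trees, minimize_information_flow, window = w)
  for (r in seq_len(mift_config$max_revision_rounds)) {
    sig <- forest_signature(trees)
    trees <- merge_close_trees(trees, mift_config$merge_radius, w)
    trees <- heal_terminal_gaps(trees, mift_config$merge_radius, w)
    trees <- do.call(c, lapply(trees, split_sharp_turns,
                               cos_threshold = mift_config$split_cos_threshold,
                               window = w))
    trees <- absorb_redundant_trees(trees, mift_config$absorb_tol,
                                    mift_config$absorb_max_nodes)
    if (identical(forest_signature(trees), sig)) break
  }
  trees
}

forest_signature <- function(trees) {
  sort(vapply(trees, function(t) nrow(t$pos), numeric(1)))
}

#' Write a reconstruction to SWC
#'
#' One tree per root; the emitted radius is the configured neurite radius.
#'
#' @param recon a `pn_reconstruction` (or plain list of `neurite_tree`s).
#' @param path output SWC path.
#' @param radius emitted radius (voxels).
#' @return `path`, invisibly.
#' @export
reconstruction_to_swc <- function(recon, path, radius = 3) {
  trees <- if (inherits(recon, "pn_reconstruction")) recon$trees else recon
  write_swc(trees_to_swc(trees, radius = radius), path)
}

#' Reconstruct every block of a phantom domain
#'
#' Convenience driver for hierarchical-fusion experiments: rasterizes the
#' ground-truth skeleton's distance field per block, reconstructs each block
#' independently, and returns the per-block tree forests with their offsets.
#'
#' @param skeleton a `gt_skeleton` for the whole domain.
#' @param block_offsets list of block origins (x, y, z).
#' @param block_shape common block extent (nx, ny, nz).
#' @param config a [pn_config()].
#' @param revise run the per-block information-flow revision.
#' @return list of blocks: each with `trees`, `offset`, `shape`.
#' @export
reconstruct_blocks <- function(skeleton, block_offsets, block_shape,
                               config = pn_config(), revise = TRUE) {
  lapply(block_offsets, function(off) {
    field <- make_distance_field_labels(skeleton, block_shape, offset = off)
    rec <- reconstruct(field, config, revise = revise)
    list(trees = rec$trees, offset = off, shape = block_shape)
  })
}
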