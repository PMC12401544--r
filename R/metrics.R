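#' Precision, recall and f1 between two skeleton point sets
#'
#' A reconstructed point is a true positive when it lies within `match_tol`
#' of some ground-truth point; recall counts the ground-truth points covered
#' within the same tolerance.
#'
#' @param recon n x 3 matrix of reconstructed skeleton points (resampled to
#'   about 1-voxel spacing).
#' @param truth m x 3 matrix of ground-truth skeleton points.
#' @param match_tol matching tolerance in voxels.
#' @return list with `precision`, `recall`, `f1`, `tp_count`, `r_count`,
#'   `g_count`.
#' @export
precision_recall_f1 <- function(recon, truth, match_tol = 4) {
  truth <- as.matrix(truth)
  recon <- as.matrix(recon)
  if (nrow(truth) == 0) stop("empty ground truth: recall undefined")
  if (nrow(recon) == 0) {
    return(list(precision = 0, recall = 0, f1 = 0, tp_count = 0L,
                r_count = 0L, g_count = nrow(truth)))
  }
  tp <- sum(cpp_nn_within(recon, truth, match_tol + 1e-9)$dist <= match_tol)
  covered <- sum(cpp_nn_within(truth, recon, match_tol + 1e-9)$dist <= match_tol)
  precision <- tp / nrow(recon)
  recall <- covered / nrow(truth)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp_count = as.integer(tp), r_count = nrow(recon),
       g_count = nrow(truth))
}

#' Ground-truth-weighted average of per-neuron scores
#'
#' @param scores list of per-neuron metric lists (as from
#'   [precision_recall_f1()]).
#' @param weights per-neuron ground-truth point counts.
#' @return list with weighted `precision`, `recall`, `f1`.
#' @export
weighted_neuron_scores <- function(scores, weights) {
  if (length(scores) == 0) stop("no neurons to average")
  w <- as.numeric(weights)
  if (sum(w) <= 0) stop("total ground-truth weight is zero")
  wavg <- function(field) {
    sum(w * vapply(scores, function(s) s[[field]], numeric(1))) / sum(w)
  }
  list(precision = wavg("precision"), recall = wavg("recall"),
       f1 = wavg("f1"))
}

#' Evaluate a reconstructed forest against per-neurite ground truth
#'
#' Each reconstructed tree is paired with the ground-truth neurite sharing
#' the most matched points (nearest neurite when nothing matches); per-neuron
#' precision/recall/f1 are then computed on the union of the trees assigned
#' to each neuron, and averaged weighted by ground-truth point counts.
#'
#' @param trees list of `neurite_tree`s.
#' @param skeleton a `gt_skeleton`.
#' @param match_tol matching tolerance (voxels).
#' @return list with `weighted` (precision/recall/f1), `per_neuron` (data
#'   frame) and `tree_assignment`.
#' @export
evaluate_reconstruction <- function(trees, skeleton, match_tol = 4) {
  G <- lapply(skeleton$polylines, function(p) resample_polyline(p, 1))
  n_neu <- length(G)
  tree_pts <- lapply(trees, function(tr) tr$pos)
  assign <- integer(length(trees))
  for (ti in seq_along(trees)) {
    counts <- vapply(G, function(g) {
      sum(cpp_nn_within(tree_pts[[ti]], g, match_tol + 1e-9)$dist <= match_tol)
    }, numeric(1))
    if (max(counts) > 0) {
      assign[ti] <- which.max(counts)
    } else {
      nd <- vapply(G, function(g) {
        min(cpp_nn_within(tree_pts[[ti]], g, 1e6)$dist)
      }, numeric(1))
      assign[ti] <- which.min(nd)
    }
  }
  scores <- vector("list", n_neu)
  for (k in seq_len(n_neu)) {
    pts <- do.call(rbind, tree_pts[assign == k])
    if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
    scores[[k]] <- precision_recall_f1(pts, G[[k]], match_tol)
  }
  weights <- vapply(G, nrow, numeric(1))
  per <- do.call(rbind, lapply(seq_len(n_neu), function(k) {
    data.frame(neuron = k, precision = scores[[k]]$precision,
               recall = scores[[k]]$recall, f1 = scores[[k]]$f1,
               g_count = weights[k])
  }))
  list(weighted = weighted_neuron_scores(scores, weights),
       per_neuron = per, tree_assignment = assign)
}

# foreground / background voxel index sets for the SNR definition:
# sigma1 = voxels of the densified skeleton; sigma2 = voxels outside the
# 3-voxel spherical expansion of the skeleton.
snr_masks <- function(volume, skeleton, mask_radius = 3) {
  dims <- dim(volume$data)
  pts <- all_skeleton_points(skeleton)
  if (is.null(pts) || nrow(pts) == 0) {
    return(list(fg = integer(0), bg = seq_along(volume$data)))
  }
  local <- sweep(resample_polylines_all(skeleton), 2,
                 as.numeric(volume$offset), "-")
  inb <- local[, 1] >= 0 & local[, 1] <= dims[3] - 1 &
         local[, 2] >= 0 & local[, 2] <= dims[2] - 1 &
         local[, 3] >= 0 & local[, 3] <= dims[1] - 1
  local <- local[inb, , drop = FALSE]
  vox <- unique_rows(round_voxels(local))
  fg <- vox[, 3] + 1 + dims[1] * (vox[, 2] + dims[2] * vox[, 1])
  d <- cpp_dist_field(as.integer(dims), local, mask_radius)
  bg <- which(!is.finite(d))
  list(fg = as.integer(fg), bg = bg)
}

resample_polylines_all <- function(skeleton, spacing = 0.9) {
  do.call(rbind, lapply(skeleton$polylines, resample_polyline,
                        spacing = spacing))
}

snr_from_masks <- function(data, masks) {
  mean_fg <- mean(data[masks$fg])
  bg <- data[masks$bg]
  mean_bg <- mean(bg)
  std_bg <- sqrt(mean((bg - mean_bg)^2))
  if (std_bg <= 0) stop("zero background standard deviation: SNR undefined")
  10 * log10(mean_fg / std_bg)
}

#' Signal-to-noise ratio of a volume given its true skeleton
#'
#' The skeleton is densified to sub-voxel spacing; its voxels form the
#' foreground support, and voxels outside a 3-voxel spherical expansion of
#' the skeleton form the background.  SNR is
#' `10 log10(mean_foreground / sd_background)` in dB.
#'
#' @param volume a [voxel_volume()].
#' @param skeleton the `gt_skeleton` of the imaged neurites.
#' @param mask_radius background exclusion radius (voxels).
#' @return SNR in dB.
#' @export
compute_snr <- function(volume, skeleton, mask_radius = 3) {
  masks <- snr_masks(volume, skeleton, mask_radius)
  if (length(masks$fg) == 0) stop("empty foreground: SNR undefined")
  snr_from_masks(volume$data, masks)
}
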