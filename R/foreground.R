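#' Extract the foreground point set from a distance-field volume
#'
#' Returns exactly the voxels whose field value is strictly greater than
#' `threshold`.  Point coordinates are global (block offset applied) and each
#' point carries an 8-bit intensity `round(255 * field)`, so the constrained
#' GMM's center-intensity floor (128) operates on the same scale as the field
#' threshold (a value just above 0.5 maps to an intensity of at least 128).
#' Volumes on the 8-bit scale (maximum value > 1) are accepted directly and
#' thresholded at `255 * threshold`.
#'
#' @param field a [voxel_volume()] with values in `[0, 1]` (or an 8-bit
#'   segmentation in `[0, 255]`).
#' @param threshold foreground threshold on the field scale.
#' @return an object of class `foreground_points`: list with `points`
#'   (n x 3 matrix of global x/y/z voxel coordinates) and `intensity`
#'   (integer vector on the 8-bit scale).
#' @export
extract_foreground_points <- function(field, threshold = 0.5) {
  arr <- field$data
  eight_bit <- max(arr) > 1
  if (eight_bit) {
    if (any(arr < 0 | arr > 255)) {
      stop("8-bit segmentation values must lie in [0, 255]")
    }
    vals <- arr / 255
  } else {
    if (any(arr < 0 | arr > 1)) stop("field values must lie in [0, 1]")
    vals <- arr
  }
  idx <- which(vals > threshold, arr.ind = TRUE)  # (z, y, x) indices
  if (nrow(idx) == 0) {
    return(foreground_points(matrix(numeric(0), ncol = 3), integer(0)))
  }
  pts <- cbind(x = idx[, 3] - 1 + field$offset[1],
               y = idx[, 2] - 1 + field$offset[2],
               z = idx[, 1] - 1 + field$offset[3])
  intens <- as.integer(round(255 * vals[idx]))
  foreground_points(pts, intens)
}

foreground_points <- function(points, intensity) {
  structure(list(points = points, intensity = intensity),
            class = "foreground_points")
}

#' @export
print.foreground_points <- function(x, ...) {
  cat(sprintf("<foreground_points: %d points>\n", nrow(x$points)))
  invisible(x)
}

#' Export foreground points as a data frame
#'
#' @param fg a `foreground_points` object.
#' @return data frame with columns `x`, `y`, `z`, `intensity`.
#' @export
foreground_table <- function(fg) {
  data.frame(x = fg$points[, 1], y = fg$points[, 2], z = fg$points[, 3],
             intensity = fg$intensity)
}
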