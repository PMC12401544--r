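# Internal geometry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(NULL)
  v / n
}

#' Resample a polyline at approximately unit spacing
#'
#' Walks a polyline (rows are ordered 3D points) and linearly interpolates so
#' that consecutive output points are at most `spacing` apart.  Vertices of
#' the input are preserved.
#'
#' @param pts numeric matrix with 3 columns (x, y, z), ordered along the curve.
#' @param spacing maximum distance between consecutive output points (voxels).
#' @return numeric matrix with 3 columns.
#' @export
resample_polyline <- function(pts, spacing = 1) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]
    b <- pts[i + 1, ]
    len <- vnorm(b - a)
    if (len <= 1e-12) next
    nseg <- ceiling(len / spacing)
    t <- seq_len(nseg) / nseg
    seg <- cbind(a[1] + t * (b[1] - a[1]),
                 a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    out[[length(out) + 1]] <- seg
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y", "z")
  res
}

# Deduplicate rows of an integer matrix.
unique_rows <- function(m) {
  if (nrow(m) == 0) return(m)
  m[!duplicated(m), , drop = FALSE]
}

# Points (n x 3, x/y/z) -> nearest-voxel integer matrix.
round_voxels <- function(pts) {
  m <- round(as.matrix(pts))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
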