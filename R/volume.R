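#' Create a voxel volume
#'
#' A `voxel_volume` wraps a 3D numeric array indexed `(z, y, x)` together with
#' an integer offset `(x, y, z)` placing the block in a global voxel frame,
#' and an (informational) physical voxel size.
#'
#' @param data 3D array, dimensions `(nz, ny, nx)`.
#' @param offset integer 3-vector `(x, y, z)`: global position of the block's
#'   voxel `(0, 0, 0)`.
#' @param voxel_size physical units per voxel (not used by the algorithms).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, offset = c(0L, 0L, 0L), voxel_size = 1) {
  if (length(dim(data)) != 3) stop("volume data must be a 3D array")
  if (any(dim(data) < 1)) stop("all volume dimensions must be >= 1")
  offset <- as.integer(round(offset))
  if (length(offset) != 3 || anyNA(offset)) {
    stop("offset must be an integer 3-vector")
  }
  structure(list(data = data, offset = offset, voxel_size = voxel_size),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume %dx%dx%d (z,y,x), offset (%d,%d,%d), range [%g, %g]>\n",
              d[1], d[2], d[3], x$offset[1], x$offset[2], x$offset[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a multi-page TIFF stack as a voxel volume
#'
#' Pages are stacked along z.  Block offsets and the stored dtype are read
#' from a plain-text sidecar file `<path>.meta` when present (TIFF offset tags
#' are unreliable across writers).
#'
#' @param path path to a multi-page TIFF.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2 && length(dim(pages[[1]])) < 3) {
    if (length(pages) == 1) stop("single-page 2D image is not a 3D volume: ", path)
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1)))) {
    stop("expected single-channel grayscale pages in ", path)
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  meta <- read_sidecar(paste0(path, ".meta"))
  dtype <- meta[["dtype"]] %||% "uint8"
  if (dtype == "float32") {
    # float pages round-trip through [0,1] scaling in the writer
    arr <- arr
  }
  offset <- if (!is.null(meta[["offset"]])) {
    as.integer(strsplit(meta[["offset"]], ",")[[1]])
  } else c(0L, 0L, 0L)
  voxel_size <- as.numeric(meta[["voxel_size"]] %||% "1")
  voxel_volume(arr, offset = offset, voxel_size = voxel_size)
}

#' Write a voxel volume to a multi-page TIFF stack
#'
#' Integer volumes (`dtype` `"uint8"`/`"uint16"`) round-trip bit-exactly;
#' `"float32"` stores the values as 32-bit floats.  The offset, dtype and
#' voxel size go to a `<path>.meta` sidecar.
#'
#' @param volume a [voxel_volume()].
#' @param path output path.
#' @param dtype one of `"uint8"`, `"uint16"`, `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype = c("uint8", "uint16", "float32")) {
  dtype <- match.arg(dtype)
  arr <- volume$data
  nz <- dim(arr)[1]
  scale <- switch(dtype, uint8 = 255, uint16 = 65535, float32 = 1)
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  if (dtype != "float32") {
    if (any(arr < 0 | arr > scale) || any(arr != round(arr))) {
      stop("volume values must be integers in [0, ", scale, "] for dtype ", dtype)
    }
  }
  pages <- lapply(seq_len(nz), function(z) {
    m <- matrix(arr[z, , ], nrow = dim(arr)[2], ncol = dim(arr)[3])
    m / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  write_sidecar(paste0(path, ".meta"), list(
    dtype = dtype,
    offset = paste(volume$offset, collapse = ","),
    voxel_size = as.character(volume$voxel_size)))
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = ":"))),
           vapply(kv, function(x) trimws(x[1]), character(1)))
}

write_sidecar <- function(path, values) {
  writeLines(sprintf("%s: %s", names(values), unlist(values)), path)
  invisible(path)
}
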