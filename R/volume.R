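#' 3D intensity volumes
#'
#' A `volume3d` is a non-negative grayscale intensity grid in an alignment
#' space. Data are stored as a numeric array with dim `(ny, nx, nz)`, so
#' `vol$data[y + 1, x + 1, z + 1]` addresses 0-based voxel `(x, y, z)` and
#' `vol$data[, , k]` is slice `k - 1` as a y-by-x image. Intensities are
#' bounded by the declared bit depth (8 or 12 bit).
#'
#' @param data Numeric array, dim `(ny, nx, nz)` matching `space$shape_xyz`
#'   reversed, all values in `[0, 2^bit_depth - 1]`.
#' @param space An [alignment_space()].
#' @param channel_id Optional channel identifier string.
#' @param bit_depth 8 (default) or 12.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, space, channel_id = NULL, bit_depth = 8L) {
  stopifnot(is_alignment_space(space))
  if (!bit_depth %in% c(8L, 12L)) abort("bit_depth must be 8 or 12")
  want <- c(space$shape_xyz[2], space$shape_xyz[1], space$shape_xyz[3])
  if (!identical(as.integer(dim(data)), as.integer(want)))
    abort(sprintf("volume dim (%s) does not match space shape (ny=%d, nx=%d, nz=%d)",
                  paste(dim(data), collapse = ","), want[1], want[2], want[3]))
  maxv <- 2^bit_depth - 1
  if (any(data < 0) || any(data > maxv))
    abort(sprintf("intensities must lie in [0, %d] for %d-bit data", maxv, bit_depth))
  structure(list(data = data, space = space, channel_id = channel_id,
                 bit_depth = as.integer(bit_depth)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s%d x %d x %d (x,y,z) voxels, %d-bit, %d foreground\n",
              if (is.null(x$channel_id)) "" else paste0("[", x$channel_id, "] "),
              x$space$shape_xyz[1], x$space$shape_xyz[2], x$space$shape_xyz[3],
              x$bit_depth, sum(x$data > 0)))
  invisible(x)
}

#' Create an all-zero volume in a space
#' @inheritParams volume3d
#' @return A [volume3d()] of zeros.
#' @export
empty_volume <- function(space, channel_id = NULL, bit_depth = 8L) {
  volume3d(array(0, c(space$shape_xyz[2], space$shape_xyz[1], space$shape_xyz[3])),
           space, channel_id, bit_depth)
}

vol_max_intensity <- function(vol) 2^vol$bit_depth - 1

#' Read a grayscale TIFF stack as a volume
#'
#' Reads a single- or multi-page grayscale TIFF whose page count and page
#' dimensions must match the declared alignment space (pages are z slices,
#' rows are y, columns are x).
#'
#' @param path TIFF file path.
#' @param space The [alignment_space()] the stack is registered to.
#' @param channel_id Optional channel identifier.
#' @param bit_depth Declared intensity bit depth (8 or 12).
#' @return A [volume3d()].
#' @export
read_stack <- function(path, space, channel_id = NULL, bit_depth = 8L) {
  if (!file.exists(path)) abort(sprintf("TIFF stack not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nx <- space$shape_xyz[1]; ny <- space$shape_xyz[2]; nz <- space$shape_xyz[3]
  if (length(pages) != nz)
    abort(sprintf("stack %s has %d slices; space %s declares %d",
                  path, length(pages), space$name, nz))
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != ny) || any(dims[2, ] != nx))
    abort(sprintf("stack %s page size %dx%d does not match space %dx%d (y,x)",
                  path, dims[1, 1], dims[2, 1], ny, nx))
  data <- array(0, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate single-channel stored as 3D
    data[, , k] <- pg
  }
  volume3d(data, space, channel_id, bit_depth)
}

#' Write a volume to a multi-page grayscale TIFF
#'
#' Inverse of [read_stack()]: one 16-bit page per z slice, storing raw
#' integer intensities losslessly.
#'
#' @param vol A [volume3d()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  nz <- vol$space$shape_xyz[3]
  pages <- lapply(seq_len(nz), function(k) vol$data[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
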