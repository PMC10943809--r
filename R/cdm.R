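#' Color depth MIP images
#'
#' A CDM is a 2D RGB image summarizing a 3D volume: a pixel is non-black iff
#' some voxel in its xy column is above the intensity threshold, and its color
#' encodes the z slice of the brightest voxel via a [build_depth_lut()] ramp,
#' with brightness linearly modulated by that voxel's intensity. Pixels are
#' stored as an integer array `(ny, nx, 3)` with values 0..255; black
#' `(0,0,0)` is background.
#'
#' @param pixels Integer array `(ny, nx, 3)`, values 0..255.
#' @param space An [alignment_space()]; `ny`, `nx` must match its y/x extent.
#' @param source_id Identifier of the neuron/channel/voxel set depicted.
#' @param variant One of `"original"`, `"flipped"`, `"combined"`.
#' @return An object of class `cdm_image`.
#' @export
cdm_image <- function(pixels, space, source_id = "", variant = "original") {
  stopifnot(is_alignment_space(space))
  variant <- match.arg(variant, c("original", "flipped", "combined"))
  want <- c(space$shape_xyz[2], space$shape_xyz[1], 3L)
  if (!identical(as.integer(dim(pixels)), want))
    abort(sprintf("CDM pixel grid (%s) does not match space (ny=%d, nx=%d, 3)",
                  paste(dim(pixels), collapse = ","), want[1], want[2]))
  if (any(pixels < 0) || any(pixels > 255)) abort("CDM pixels must be 8-bit (0..255)")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, space = space, source_id = source_id,
                 variant = variant),
            class = "cdm_image")
}

#' @export
print.cdm_image <- function(x, ...) {
  cat(sprintf("<cdm_image> '%s' (%s): %d x %d px, %d foreground\n",
              x$source_id, x$variant, x$space$shape_xyz[1], x$space$shape_xyz[2],
              sum(cdm_value(x) > 0)))
  invisible(x)
}

# per-pixel brightness (HSV value channel, max of R,G,B) as ny x nx matrix
cdm_value <- function(cdm) pmax(cdm$pixels[, , 1], cdm$pixels[, , 2], cdm$pixels[, , 3])

#' Foreground mask and decoded depth map of a CDM
#'
#' `cdm_foreground()` returns the logical ny x nx mask of pixels whose
#' brightness (max RGB channel) is at least `threshold`. `cdm_depth_map()`
#' decodes every foreground pixel's color to its 0-based z slice
#' (`NA` elsewhere).
#'
#' @param cdm A [cdm_image()].
#' @param threshold Minimum brightness (0..255) for a pixel to count as
#'   foreground.
#' @param lut The [build_depth_lut()] used to encode the image.
#' @return Logical matrix / integer matrix, both `ny` x `nx`.
#' @export
cdm_foreground <- function(cdm, threshold = 1) cdm_value(cdm) >= threshold

#' @rdname cdm_foreground
#' @export
cdm_depth_map <- function(cdm, lut) {
  d <- decode_depth_rgb(as.vector(cdm$pixels[, , 1]), as.vector(cdm$pixels[, , 2]),
                        as.vector(cdm$pixels[, , 3]), lut)
  matrix(d, nrow = dim(cdm$pixels)[1])
}

#' Encode a volume as a color depth MIP
#'
#' For each xy column, finds the maximum-intensity voxel; if its intensity
#' exceeds `intensity_threshold` the pixel gets the LUT color of that voxel's
#' slice, scaled linearly by intensity relative to the volume's bit-depth
#' maximum. Ties between equal maxima are broken toward the shallower
#' (smaller z) slice, deterministically.
#'
#' @param vol A [volume3d()] whose z extent equals `lut$n_slices`.
#' @param lut A [build_depth_lut()].
#' @param intensity_threshold Columns whose maximum intensity is `<=` this
#'   value become background. Default 0: any positive voxel is signal.
#' @param source_id,variant Passed to [cdm_image()].
#' @return A [cdm_image()].
#' @export
encode_volume <- function(vol, lut, intensity_threshold = 0,
                          source_id = vol$channel_id %||% "", variant = "original") {
  stopifnot(inherits(vol, "volume3d"), inherits(lut, "depth_lut"))
  nz <- vol$space$shape_xyz[3]
  if (nz != lut$n_slices)
    abort(sprintf("volume has %d slices but LUT encodes %d", nz, lut$n_slices))
  ny <- dim(vol$data)[1]; nx <- dim(vol$data)[2]
  best <- matrix(-Inf, ny, nx)
  argz <- matrix(0L, ny, nx)
  for (k in seq_len(nz)) {            # strict '>' keeps the shallowest tie
    sl <- vol$data[, , k]
    upd <- sl > best
    best[upd] <- sl[upd]
    argz[upd] <- k - 1L
  }
  fg <- best > intensity_threshold
  maxI <- vol_max_intensity(vol)
  px <- array(0L, c(ny, nx, 3L))
  if (any(fg)) {
    idx <- which(fg)
    frac <- best[idx] / maxI
    cols <- lut$colors[argz[idx] + 1L, , drop = FALSE]
    px[idx] <- as.integer(round(cols[, 1] * frac))
    px[idx + ny * nx] <- as.integer(round(cols[, 2] * frac))
    px[idx + 2L * ny * nx] <- as.integer(round(cols[, 3] * frac))
  }
  cdm_image(px, vol$space, source_id = source_id, variant = variant)
}

#' Read and write CDM PNG images
#'
#' CDMs are stored as 8-bit RGB PNGs; the round trip is bit-exact. Reading a
#' grayscale or paletted PNG raises a format error; an alpha channel, if
#' present, is dropped.
#'
#' @param cdm A [cdm_image()].
#' @param path PNG file path.
#' @param space The [alignment_space()] the image belongs to.
#' @param source_id,variant Metadata attached to the loaded image.
#' @return `read_cdm_png()` returns a [cdm_image()]; `write_cdm_png()`
#'   returns `path` invisibly.
#' @export
write_cdm_png <- function(cdm, path) {
  stopifnot(inherits(cdm, "cdm_image"))
  png::writePNG(cdm$pixels / 255, path)
  invisible(path)
}

#' @rdname write_cdm_png
#' @export
read_cdm_png <- function(path, space, source_id = "", variant = "original") {
  if (!file.exists(path)) abort(sprintf("PNG not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || !dim(img)[3] %in% c(3L, 4L))
    abort(sprintf("%s is not an RGB PNG", path))
  px <- array(as.integer(round(img[, , 1:3] * 255)), c(dim(img)[1], dim(img)[2], 3L))
  cdm_image(px, space, source_id = source_id, variant = variant)
}

# x-index mapping for reflection about the space midline; returns the mirror
# target column (1-based) for each source column, NA when it falls outside
mirror_x_map <- function(space) {
  nx <- space$shape_xyz[1]
  mid_vox <- space$midline_x_um / space$voxel_size_um[1]
  x <- seq_len(nx) - 1L                       # 0-based
  xm <- as.integer(round(2 * mid_vox - 1 - x))
  xm[xm < 0L | xm >= nx] <- NA_integer_
  xm + 1L
}

#' Mirror and mirror-combine CDMs across the midline
#'
#' `mirror_cdm()` reflects a CDM about the alignment space's x midline (the
#' left/right brain axis). `combine_mirror()` unions the original with its
#' mirror; where both have foreground the brighter pixel wins (MIP
#' semantics). The combined variant emulates bilateral expression from a
#' single-hemisphere neuron. With the default centre midline, mirroring is an
#' exact involution.
#'
#' @param cdm A [cdm_image()].
#' @return A [cdm_image()] with `variant = "flipped"` / `"combined"`.
#' @export
mirror_cdm <- function(cdm) {
  stopifnot(inherits(cdm, "cdm_image"))
  xm <- mirror_x_map(cdm$space)
  px <- array(0L, dim(cdm$pixels))
  ok <- !is.na(xm)
  px[, xm[ok], ] <- cdm$pixels[, which(ok), ]
  cdm_image(px, cdm$space, source_id = cdm$source_id,
            variant = if (cdm$variant == "flipped") "original" else "flipped")
}

#' @rdname mirror_cdm
#' @export
combine_mirror <- function(cdm) {
  m <- mirror_cdm(cdm)
  keep_m <- cdm_value(m) > cdm_value(cdm)   # brighter pixel wins on overlap
  px <- cdm$pixels
  idx <- which(keep_m)
  n <- prod(dim(px)[1:2])
  for (ch in 0:2) px[idx + ch * n] <- m$pixels[idx + ch * n]
  cdm_image(px, cdm$space, source_id = cdm$source_id, variant = "combined")
}

#' Does an object cross the brain midline?
#'
#' True iff foreground exists strictly on both sides of the midline, each at
#' least `band_um` away from it. Works on skeletons (node coordinates),
#' volumes (foreground voxels) and CDMs (foreground pixels).
#'
#' @param x A [skeleton()], [volume3d()], [cdm_image()] or voxel set.
#' @param band_um Half-width (um) of the midline exclusion band.
#' @param ... Method arguments.
#' @return Logical scalar.
#' @export
crosses_midline <- function(x, band_um = 5, ...) UseMethod("crosses_midline")

both_sides <- function(x_um, midline, band)
  any(x_um < midline - band) && any(x_um > midline + band)

#' @export
crosses_midline.skeleton <- function(x, band_um = 5, ...)
  both_sides(x$nodes$x, x$space$midline_x_um, band_um)

#' @export
crosses_midline.volume3d <- function(x, band_um = 5, ...) {
  fg <- which(apply(x$data > 0, 2L, any))       # columns (x) with any signal
  if (length(fg) == 0L) return(FALSE)
  both_sides(voxel_to_um(fg - 1L, x$space$voxel_size_um[1]),
             x$space$midline_x_um, band_um)
}

#' @export
crosses_midline.cdm_image <- function(x, band_um = 5, ...) {
  fg <- which(apply(cdm_value(x) > 0, 2L, any))
  if (length(fg) == 0L) return(FALSE)
  both_sides(voxel_to_um(fg - 1L, x$space$voxel_size_um[1]),
             x$space$midline_x_um, band_um)
}

#' @export
crosses_midline.voxel_set <- function(x, band_um = 5, ...)
  both_sides(voxel_to_um(x$voxels$x, x$space$voxel_size_um[1]),
             x$space$midline_x_um, band_um)
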