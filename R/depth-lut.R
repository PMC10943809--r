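#' Depth-to-color lookup table
#'
#' A CDM encodes the z position of the brightest voxel in each xy column as a
#' pixel color. The lookup table maps slice 0 (anterior) to pure blue
#' (hue 240 degrees) and the last slice (posterior) to pure red (hue 0), with a
#' monotone hue ramp at full saturation and value in between. The ramp is
#' built by walking the exact integer path through 8-bit RGB hue space
#' (blue -> cyan -> green -> yellow -> red; 4 x 255 unit steps + 1 = 1021
#' distinct colors) and sampling `n_slices` evenly spaced positions, which
#' guarantees pairwise-distinct colors and hence an exact decode.
#'
#' @param n_slices Number of z slices (2 to 1021; the 8-bit hue path cannot
#'   supply more distinct colors).
#' @return An object of class `depth_lut` with fields `n_slices` and `colors`
#'   (integer matrix, `n_slices` x 3, RGB in 0..255).
#' @examples
#' lut <- build_depth_lut(64)
#' lut$colors[1, ]   # pure blue, slice 0
#' lut$colors[64, ]  # pure red, last slice
#' @export
build_depth_lut <- function(n_slices) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 2L) abort("n_slices must be an integer >= 2")
  capacity <- 4L * 255L + 1L  # number of distinct colors on the 240->0 hue path
  if (n_slices > capacity)
    abort(sprintf("n_slices = %d exceeds the distinct-color capacity (%d) of the 8-bit hue ramp",
                  n_slices, capacity))
  # position p in 0..1020 along the hue path, hue = 240 * (1 - p/1020)
  hue_path_color <- function(p) {
    seg <- pmin(p %/% 255L, 3L)
    t <- p - seg * 255L
    r <- ifelse(seg < 2L, 0L, ifelse(seg == 2L, t, 255L))
    g <- ifelse(seg == 0L, t, ifelse(seg == 3L, 255L - t, 255L))
    b <- ifelse(seg == 0L, 255L, ifelse(seg == 1L, 255L - t, 0L))
    cbind(r, g, b)
  }
  p <- as.integer(round((seq_len(n_slices) - 1L) * (capacity - 1L) / (n_slices - 1L)))
  colors <- hue_path_color(p)
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  structure(list(n_slices = n_slices, colors = colors), class = "depth_lut")
}

#' @export
print.depth_lut <- function(x, ...) {
  cat(sprintf("<depth_lut> %d slices, blue (%s) -> red (%s)\n", x$n_slices,
              paste(x$colors[1, ], collapse = ","),
              paste(x$colors[x$n_slices, ], collapse = ",")))
  invisible(x)
}

lut_key <- function(r, g, b) r * 65536 + g * 256 + b

#' Decode a CDM pixel color back to its slice index
#'
#' Inverse of the depth encoding. The pixel is first normalized for intensity
#' scaling (the brightest channel is rescaled to 255, undoing the linear
#' value-channel modulation applied by [encode_volume()]), then matched
#' against the LUT: exactly if possible, otherwise to the nearest LUT color
#' within a small guard distance (rounding during intensity scaling can
#' perturb channels by a few units). Black is background.
#'
#' @param color Integer RGB triple (0..255), or an n x 3 matrix of them.
#' @param lut A [build_depth_lut()] table.
#' @param guard Maximum Euclidean RGB distance accepted when no exact match
#'   exists; colors farther than this from every LUT entry are not depth
#'   colors and raise a decode error.
#' @return 0-based slice index (vector for matrix input); `NA` for black
#'   (background) pixels.
#' @export
decode_depth <- function(color, lut, guard = 8) {
  if (is.null(dim(color))) color <- matrix(as.integer(color), ncol = 3L)
  out <- decode_depth_rgb(color[, 1], color[, 2], color[, 3], lut, guard, strict = TRUE)
  if (length(out) == 1L) out[[1]] else out
}

# vectorized decode on raw channel vectors; strict = error on unmapped colors,
# otherwise unmapped foreground decodes to NA
decode_depth_rgb <- function(r, g, b, lut, guard = 8, strict = FALSE) {
  out <- rep(NA_integer_, length(r))
  fg <- which(r + g + b > 0)
  if (length(fg) == 0L) return(out)
  v <- pmax(r[fg], g[fg], b[fg])
  rn <- as.integer(round(r[fg] * 255 / v))
  gn <- as.integer(round(g[fg] * 255 / v))
  bn <- as.integer(round(b[fg] * 255 / v))
  keys <- lut_key(lut$colors[, 1], lut$colors[, 2], lut$colors[, 3])
  hit <- match(lut_key(rn, gn, bn), keys)
  miss <- which(is.na(hit))
  if (length(miss) > 0L) {
    # nearest LUT color within the guard radius, on the normalized pixel
    cc <- lut$colors
    for (i in miss) {
      d2 <- (cc[, 1] - rn[i])^2 + (cc[, 2] - gn[i])^2 + (cc[, 3] - bn[i])^2
      j <- which.min(d2)
      if (d2[j] <= guard^2) hit[i] <- j
      else if (strict)
        abort(sprintf("color (%d,%d,%d) does not decode to any depth slice",
                      r[fg[i]], g[fg[i]], b[fg[i]]))
    }
  }
  out[fg] <- as.integer(hit - 1L)
  out
}
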