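#' Define an alignment space
#'
#' An alignment space is the shared template grid into which every image and
#' skeleton has been registered, so that voxel coordinates are directly
#' comparable across samples and modalities. All physical coordinates in this
#' package are micrometres in such a space; voxel indices are 0-based, with a
#' physical coordinate `c` mapping to voxel `floor(c / voxel_size)` and a
#' voxel index `i` mapping back to the voxel-centre coordinate
#' `(i + 0.5) * voxel_size` (so a round trip moves a point by at most half a
#' voxel per axis).
#'
#' @param name Character scalar naming the space (e.g. a template name).
#' @param shape_xyz Integer vector of length 3: grid extent in voxels along
#'   x (width), y (height), z (depth/slices).
#' @param voxel_size_um Positive numeric vector of length 3: micrometres per
#'   voxel along x, y, z.
#' @param midline_x_um Physical x position (um) of the left/right midline used
#'   for mirror augmentation. Defaults to the centre of the x extent.
#'
#' @return An object of class `alignment_space`.
#' @examples
#' toy_space()
#' alignment_space("demo", c(64, 32, 16), c(1, 1, 1))
#' @export
alignment_space <- function(name, shape_xyz, voxel_size_um = c(1, 1, 1),
                            midline_x_um = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  shape_xyz <- as.integer(shape_xyz)
  if (length(shape_xyz) != 3L || any(is.na(shape_xyz)) || any(shape_xyz < 1L))
    abort("`shape_xyz` must be three integers >= 1")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    abort("`voxel_size_um` must be three positive numbers")
  width_um <- shape_xyz[1] * voxel_size_um[1]
  midline_x_um <- midline_x_um %||% (width_um / 2)
  if (!is.numeric(midline_x_um) || length(midline_x_um) != 1L ||
      midline_x_um < 0 || midline_x_um > width_um)
    abort("`midline_x_um` must lie within [0, width_um]")
  structure(
    list(name = name, shape_xyz = shape_xyz, voxel_size_um = voxel_size_um,
         midline_x_um = as.numeric(midline_x_um)),
    class = "alignment_space"
  )
}

#' Default toy alignment space
#'
#' A 256 x 128 x 64 voxel space at 1 um isotropic resolution. At this
#' resolution the shape-scoring constants are directly interpretable:
#' the 12 um XY support radius is 12 pixels and the 40 um Z mismatch bound is
#' 40 slices.
#'
#' @param name Space name.
#' @return An [alignment_space()].
#' @export
toy_space <- function(name = "TOY_UNISEX_1UM") {
  alignment_space(name, c(256L, 128L, 64L), c(1, 1, 1))
}

#' @export
print.alignment_space <- function(x, ...) {
  cat(sprintf(
    "<alignment_space> %s: %d x %d x %d voxels @ (%g, %g, %g) um, midline x = %g um\n",
    x$name, x$shape_xyz[1], x$shape_xyz[2], x$shape_xyz[3],
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3], x$midline_x_um))
  invisible(x)
}

is_alignment_space <- function(x) inherits(x, "alignment_space")

same_space <- function(a, b) {
  identical(a$shape_xyz, b$shape_xyz) &&
    isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um)) &&
    isTRUE(all.equal(a$midline_x_um, b$midline_x_um))
}

check_same_space <- function(a, b, what = "objects") {
  if (!same_space(a, b))
    abort(sprintf("%s are in different alignment spaces (%s vs %s)",
                  what, a$name, b$name))
  invisible(TRUE)
}

# um <-> 0-based voxel index, per-axis
um_to_voxel <- function(coord_um, voxel_size_um) as.integer(floor(coord_um / voxel_size_um))
voxel_to_um <- function(idx, voxel_size_um) (idx + 0.5) * voxel_size_um

#' Read and write alignment-space config files
#'
#' Alignment spaces are declared in small YAML config files with keys
#' `name`, `shape_xyz`, `voxel_size_um` and optional `midline_x_um`.
#'
#' @param path File path.
#' @param space An [alignment_space()] (for writing).
#' @return `read_space_config()` returns an [alignment_space()];
#'   `write_space_config()` returns `path` invisibly.
#' @export
read_space_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("space config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (k in c("name", "shape_xyz", "voxel_size_um"))
    if (is.null(cfg[[k]])) abort(sprintf("space config missing key '%s'", k))
  alignment_space(cfg$name, unlist(cfg$shape_xyz), unlist(cfg$voxel_size_um),
                  cfg$midline_x_um)
}

#' @rdname read_space_config
#' @export
write_space_config <- function(space, path) {
  stopifnot(is_alignment_space(space))
  yaml::write_yaml(list(
    name = space$name,
    shape_xyz = as.integer(space$shape_xyz),
    voxel_size_um = as.numeric(space$voxel_size_um),
    midline_x_um = space$midline_x_um), path)
  invisible(path)
}
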