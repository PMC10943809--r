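#' Segmentation parameters
#'
#' Parameters for direction-selective local thresholding (DSLT) and junk
#' filtering. DSLT estimates the local background at each voxel as the mean
#' intensity along an oriented line kernel and calls the voxel foreground if
#' it exceeds that estimate by `local_offset` in at least
#' `min_directions_hit` of the `n_directions` orientations. A voxel inside a
#' thin neurite is brighter than the background along most lines crossing it,
#' while lines running along the neurite see the neurite itself and fail the
#' test — hence the directional vote.
#'
#' @param line_kernel_length_um Length (um) of the oriented line kernel.
#' @param n_directions Number of 3D line orientations (the 13 symmetric axes
#'   of the 26-neighbourhood).
#' @param local_offset Intensity margin above the local mean.
#' @param min_directions_hit Minimum number of orientations that must vote
#'   foreground.
#' @param min_voxels Components smaller than this are junk.
#' @param max_sets_per_channel Keep at most this many largest components.
#' @param min_bbox_extent_um Junk filter: smallest allowed maximum
#'   bounding-box edge (um).
#' @param max_elongation Junk filter: largest allowed ratio of longest to
#'   shortest bounding-box edge (`Inf` disables).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(line_kernel_length_um = 10,
                                n_directions = 13L,
                                local_offset = 20,
                                min_directions_hit = 9L,
                                min_voxels = 100L,
                                max_sets_per_channel = 10L,
                                min_bbox_extent_um = 10,
                                max_elongation = Inf) {
  if (n_directions < 3L) abort("n_directions must be >= 3")
  if (min_voxels < 1L) abort("min_voxels must be >= 1")
  if (max_sets_per_channel < 1L) abort("max_sets_per_channel must be >= 1")
  structure(list(line_kernel_length_um = line_kernel_length_um,
                 n_directions = as.integer(n_directions),
                 local_offset = local_offset,
                 min_directions_hit = as.integer(min_directions_hit),
                 min_voxels = as.integer(min_voxels),
                 max_sets_per_channel = as.integer(max_sets_per_channel),
                 min_bbox_extent_um = min_bbox_extent_um,
                 max_elongation = max_elongation),
            class = "segmentation_params")
}

# the 13 unique axes of the 26-neighbourhood as integer (dx, dy, dz) steps
dslt_directions <- function(n_directions = 13L) {
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  dirs[seq_len(min(n_directions, nrow(dirs))), , drop = FALSE]
}

# shift a (ny, nx, nz) array by (dy, dx, dz) voxels, zero padding
shift3d <- function(arr, dy, dx, dz) {
  d <- dim(arr)
  out <- array(0, d)
  ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
  ysrc <- ys - dy; xsrc <- xs - dx; zsrc <- zs - dz
  yok <- ysrc >= 1 & ysrc <= d[1]; xok <- xsrc >= 1 & xsrc <= d[2]; zok <- zsrc >= 1 & zsrc <= d[3]
  if (!any(yok) || !any(xok) || !any(zok)) return(out)
  out[ys[yok], xs[xok], zs[zok]] <- arr[ysrc[yok], xsrc[xok], zsrc[zok]]
  out
}

#' Direction-selective local thresholding segmentation
#'
#' Computes a binary foreground mask for a volume: a voxel is foreground iff
#' its intensity exceeds the local background estimate (mean intensity along
#' an oriented line kernel centred on the voxel, out-of-bounds samples
#' excluded) plus `local_offset`, in at least `min_directions_hit`
#' orientations. Adding a constant to the whole volume leaves the mask
#' unchanged (the test is a local contrast), and the result is fully
#' deterministic.
#'
#' @param vol A [volume3d()].
#' @param params A [segmentation_params()].
#' @return Logical array with the volume's dimensions.
#' @export
dslt_segment <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "volume3d"))
  vs <- vol$space$voxel_size_um
  dirs <- dslt_directions(params$n_directions)
  d <- dim(vol$data)
  votes <- array(0L, d)
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    step_um <- sqrt(sum((u * vs[c(1, 2, 3)])^2))
    h <- max(1L, floor(params$line_kernel_length_um / (2 * step_um)))
    if (2L * h + 1L > min(d)) abort("line kernel is longer than the volume")
    acc <- array(0, d)
    for (t in -h:h) {
      if (t == 0L) acc <- acc + vol$data
      else acc <- acc + shift3d(vol$data, t * u[2], t * u[1], t * u[3])
    }
    cnt <- dslt_count_array(d, u, h)   # in-bounds sample counts (geometry only)
    hit <- vol$data > acc / cnt + params$local_offset
    votes <- votes + hit
  }
  votes >= params$min_directions_hit
}

# cache of in-bounds sample-count arrays, keyed by dims/direction/half-length;
# the count at a voxel depends only on geometry, not on the data
.dslt_cache <- new.env(parent = emptyenv())

dslt_count_array <- function(d, u, h) {
  key <- paste(c(d, u, h), collapse = "_")
  hit <- .dslt_cache[[key]]
  if (!is.null(hit)) return(hit)
  # count along each axis independently: sample t is in-bounds iff it is
  # in-bounds along every axis, and in-bounds-ness is separable per axis
  cnt <- array(0, d)
  axis_ok <- function(n, step) {
    # for positions p = 1..n, how many t in -h..h satisfy 1 <= p + t*step <= n
    if (step == 0L) return(matrix(TRUE, n, 2L * h + 1L))
    outer(seq_len(n), (-h:h) * step, function(p, s) p + s >= 1L & p + s <= n)
  }
  oky <- axis_ok(d[1], u[2]); okx <- axis_ok(d[2], u[1]); okz <- axis_ok(d[3], u[3])
  for (ti in seq_len(2L * h + 1L)) {
    block <- outer(oky[, ti], okx[, ti]) # ny x nx
    for (z in seq_len(d[3])) if (okz[z, ti]) cnt[, , z] <- cnt[, , z] + block
  }
  .dslt_cache[[key]] <- cnt
  cnt
}

#' Voxel sets
#'
#' A voxel set is one connected component of a segmentation mask: a tibble of
#' 0-based voxel coordinates with intensities, plus shape descriptors used by
#' the junk filter (voxel count, bounding-box extents in um, elongation =
#' longest / shortest bounding-box edge).
#'
#' @param voxels Tibble with columns `x`, `y`, `z` (0-based) and `intensity`.
#' @param space The [alignment_space()].
#' @param id Identifier string.
#' @return Object of class `voxel_set` with a `descriptor` field.
#' @export
voxel_set <- function(voxels, space, id = "") {
  stopifnot(is_alignment_space(space))
  voxels <- as_tibble(voxels)
  if (nrow(voxels) < 1L) abort("a voxel set must contain at least one voxel")
  sh <- space$shape_xyz
  if (any(voxels$x < 0 | voxels$x >= sh[1] | voxels$y < 0 | voxels$y >= sh[2] |
          voxels$z < 0 | voxels$z >= sh[3]))
    abort("voxel coordinates outside the alignment space")
  ext <- c((diff(range(voxels$x)) + 1) * space$voxel_size_um[1],
           (diff(range(voxels$y)) + 1) * space$voxel_size_um[2],
           (diff(range(voxels$z)) + 1) * space$voxel_size_um[3])
  structure(list(
    voxels = voxels, space = space, id = id,
    descriptor = list(n_voxels = nrow(voxels), bbox_extent_um = ext,
                      elongation = max(ext) / min(ext))),
    class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> '%s': %d voxels, bbox %s um, elongation %.1f\n",
              x$id, x$descriptor$n_voxels,
              paste(round(x$descriptor$bbox_extent_um, 1), collapse = " x "),
              x$descriptor$elongation))
  invisible(x)
}

#' Label 26-connected components of a mask
#'
#' Flood-fills the foreground of a binary mask with 26-connectivity (so
#' diagonal voxel contacts join — thin neurites survive) and returns one
#' [voxel_set()] per component, ordered by size descending, ties broken by
#' the lexicographically smallest (x, y, z) coordinate.
#'
#' @param mask Logical array `(ny, nx, nz)`.
#' @param space The [alignment_space()].
#' @param volume Optional [volume3d()] supplying per-voxel intensities
#'   (otherwise intensity 1).
#' @param id_prefix Component ids are `<id_prefix>_<k>` after ordering.
#' @return List of [voxel_set()]s (possibly empty).
#' @export
label_components <- function(mask, space, volume = NULL, id_prefix = "set") {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  labels <- integer(length(mask))
  # 26-neighbourhood linear-index offsets with coordinate guards
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  lin_off <- offs$dy + offs$dx * d[1] + offs$dz * d[1] * d[2]
  coord <- function(idx) {             # 1-based (y, x, z) of linear indices
    idx0 <- idx - 1L
    y <- idx0 %% d[1]
    x <- (idx0 %/% d[1]) %% d[2]
    z <- idx0 %/% (d[1] * d[2])
    cbind(y + 1L, x + 1L, z + 1L)
  }
  lab <- 0L
  comp_members <- list()
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    members <- seed
    while (length(frontier) > 0L) {
      fc <- coord(frontier)
      nbr_all <- integer(0)
      for (o in seq_along(lin_off)) {
        ny <- fc[, 1] + offs$dy[o]; nx <- fc[, 2] + offs$dx[o]; nz <- fc[, 3] + offs$dz[o]
        ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
        if (!any(ok)) next
        nbr_all <- c(nbr_all, frontier[ok] + lin_off[o])
      }
      nbr_all <- unique(nbr_all)
      nbr_all <- nbr_all[mask[nbr_all] & labels[nbr_all] == 0L]
      labels[nbr_all] <- lab
      members <- c(members, nbr_all)
      frontier <- nbr_all
    }
    comp_members[[lab]] <- members
  }
  sets <- lapply(comp_members, function(m) {
    cc <- coord(m)
    tb <- tibble(x = cc[, 2] - 1L, y = cc[, 1] - 1L, z = cc[, 3] - 1L,
                 intensity = if (is.null(volume)) rep(1, length(m)) else volume$data[m])
    tb[order(tb$x, tb$y, tb$z), ]
  })
  # deterministic order: size desc, then lexical min (x, y, z)
  key <- t(vapply(sets, function(tb) c(-nrow(tb), tb$x[1], tb$y[1], tb$z[1]), numeric(4)))
  ord <- order(key[, 1], key[, 2], key[, 3], key[, 4])
  lapply(seq_along(ord), function(k)
    voxel_set(sets[[ord[k]]], space, id = sprintf("%s_%d", id_prefix, k)))
}

#' Junk-filter voxel sets
#'
#' Drops components that fail the size or shape thresholds (too few voxels,
#' bounding box smaller than `min_bbox_extent_um` along its longest edge, or
#' elongation above `max_elongation`), then keeps at most
#' `max_sets_per_channel` of the largest survivors. Idempotent, never
#' increases the set count, preserves the deterministic input order.
#'
#' @param sets List of [voxel_set()]s as returned by [label_components()].
#' @param params A [segmentation_params()].
#' @return Filtered list of [voxel_set()]s.
#' @export
filter_components <- function(sets, params = segmentation_params()) {
  keep <- vapply(sets, function(s) {
    d <- s$descriptor
    d$n_voxels >= params$min_voxels &&
      max(d$bbox_extent_um) >= params$min_bbox_extent_um &&
      d$elongation <= params$max_elongation
  }, logical(1))
  head(sets[keep], params$max_sets_per_channel)
}

#' Encode voxel sets as per-set CDMs
#'
#' Renders each voxel set alone into an otherwise empty volume and encodes it
#' as a CDM, so one multi-neuron LM channel yields one searchable image per
#' segmented neuron.
#'
#' @param sets List of [voxel_set()]s.
#' @param lut A [build_depth_lut()] with the space's slice count.
#' @param space The [alignment_space()].
#' @param bit_depth Intensity bit depth used for scaling.
#' @return List of [cdm_image()]s, one per set, in input order.
#' @export
voxelsets_to_cdms <- function(sets, lut, space, bit_depth = 8L) {
  lapply(sets, function(s) {
    vol <- empty_volume(space, bit_depth = bit_depth)
    idx <- cbind(s$voxels$y + 1L, s$voxels$x + 1L, s$voxels$z + 1L)
    vol$data[idx] <- pmin(s$voxels$intensity, vol_max_intensity(vol))
    encode_volume(vol, lut, source_id = s$id)
  })
}
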