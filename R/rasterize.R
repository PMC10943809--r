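#' Rasterize a skeleton into a volume
#'
#' Draws the skeleton as a union of capsules: every voxel whose centre lies
#' within `radius_um` of any edge segment (or of any node, covering isolated
#' nodes and capsule end caps) is set to the maximum intensity of the
#' declared bit depth. Using a fixed radius rather than the per-node SWC
#' radius is deliberate: it controls the apparent diameter of EM neurons so
#' their CDMs are comparable to LM signal.
#'
#' @param skel A [skeleton()].
#' @param space Target [alignment_space()] (defaults to the skeleton's).
#' @param radius_um Tube radius in micrometres (> 0).
#' @param bit_depth Intensity bit depth of the output volume.
#' @return A [volume3d()]; a warning is issued (and geometry clipped) if the
#'   skeleton extends beyond the space bounds.
#' @export
rasterize_skeleton <- function(skel, space = skel$space, radius_um, bit_depth = 8L) {
  stopifnot(inherits(skel, "skeleton"))
  if (!is.numeric(radius_um) || radius_um <= 0) abort("radius_um must be > 0")
  vs <- space$voxel_size_um
  nx <- space$shape_xyz[1]; ny <- space$shape_xyz[2]; nz <- space$shape_xyz[3]
  nodes <- skel$nodes
  lim_um <- space$shape_xyz * vs
  if (any(nodes$x < 0 | nodes$y < 0 | nodes$z < 0 |
          nodes$x > lim_um[1] | nodes$y > lim_um[2] | nodes$z > lim_um[3]))
    warn("skeleton extends beyond the alignment space; clipping to bounds")

  data <- array(0, c(ny, nx, nz))
  maxI <- 2^bit_depth - 1
  # segments: each node with a real parent, as (a, b) um endpoints; plus every
  # node as a degenerate segment so single nodes and end caps are filled
  a_list <- lapply(seq_len(nrow(nodes)), function(i) c(nodes$x[i], nodes$y[i], nodes$z[i]))
  b_list <- a_list
  has_par <- which(nodes$parent_id != -1L)
  for (i in has_par) {
    j <- match(nodes$parent_id[i], nodes$node_id)
    a_list <- c(a_list, list(c(nodes$x[i], nodes$y[i], nodes$z[i])))
    b_list <- c(b_list, list(c(nodes$x[j], nodes$y[j], nodes$z[j])))
  }

  for (s in seq_along(a_list)) {
    a <- a_list[[s]]; b <- b_list[[s]]
    lo <- pmax(floor((pmin(a, b) - radius_um) / vs), 0)
    hi <- pmin(floor((pmax(a, b) + radius_um) / vs), c(nx, ny, nz) - 1L)
    if (any(hi < lo)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    # voxel-centre coordinates of the candidate box
    cx <- voxel_to_um(xs, vs[1]); cy <- voxel_to_um(ys, vs[2]); cz <- voxel_to_um(zs, vs[3])
    g <- expand.grid(y = cy, x = cx, z = cz)  # order matches array linear index
    d2 <- point_segment_dist2(g$x, g$y, g$z, a, b)
    hit <- d2 <= radius_um^2
    if (any(hit)) {
      gi <- expand.grid(y = ys + 1L, x = xs + 1L, z = zs + 1L)
      data[cbind(gi$y[hit], gi$x[hit], gi$z[hit])] <- maxI
    }
  }
  volume3d(data, space, channel_id = NULL, bit_depth = bit_depth)
}

# squared distance from points (px,py,pz) to segment a-b (vectorized on points)
point_segment_dist2 <- function(px, py, pz, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2)
  }
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 + (pz - (a[3] + t * ab[3]))^2
}
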