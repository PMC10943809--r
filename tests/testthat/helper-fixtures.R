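# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use naive per-pixel / per-voxel loops so they share no
# code path with the package implementation.

mini_space <- function() alignment_space("MINI_1UM", c(96L, 64L, 32L), c(1, 1, 1))
flat_space <- function(nx = 32L, ny = 32L, nz = 16L)
  alignment_space("FLAT", c(nx, ny, nz), c(1, 1, 1))

# build a CDM directly from known pixel depths: coords is a data.frame with
# 0-based x, y, depth and optional intensity (0..255)
make_depth_cdm <- function(coords, space, lut, source_id = "q", intensity = 255L) {
  px <- array(0L, c(space$shape_xyz[2], space$shape_xyz[1], 3L))
  n <- prod(dim(px)[1:2])
  inten <- if (is.null(coords$intensity)) rep(intensity, nrow(coords)) else coords$intensity
  for (i in seq_len(nrow(coords))) {
    col <- round(lut$colors[coords$depth[i] + 1L, ] * inten[i] / 255)
    idx <- (coords$y[i] + 1L) + coords$x[i] * dim(px)[1]
    px[idx] <- as.integer(col[1]); px[idx + n] <- as.integer(col[2])
    px[idx + 2L * n] <- as.integer(col[3])
  }
  cdm_image(px, space, source_id = source_id)
}

# random sparse depth CDM plus its ground-truth depth table
random_depth_cdm <- function(space, lut, n_px, seed, source_id = "r") {
  set.seed(seed)
  nx <- space$shape_xyz[1]; ny <- space$shape_xyz[2]; nz <- space$shape_xyz[3]
  pick <- sample(nx * ny, n_px)
  coords <- data.frame(x = (pick - 1L) %% nx, y = (pick - 1L) %/% nx,
                       depth = sample(0:(nz - 1L), n_px, replace = TRUE))
  list(cdm = make_depth_cdm(coords, space, lut, source_id), coords = coords)
}

# ---- oracles ---------------------------------------------------------------

# depth-table brute-force pair scorer: all shifts, optional mirror of target;
# works on ground-truth coordinate tables, never on decoded pixels
oracle_pair_score <- function(qc, tc, space, xy_shift, z_tol, try_flip = FALSE) {
  nx <- space$shape_xyz[1]
  tgt_key <- function(coords) {
    k <- coords$x * 10000 + coords$y
    setNames(coords$depth, k)
  }
  variants <- list(tc)
  if (try_flip) {
    tf <- tc; tf$x <- nx - 1L - tf$x
    variants <- c(variants, list(tf))
  }
  best <- -1L
  for (vt in variants) {
    tk <- tgt_key(vt)
    for (dx in -xy_shift:xy_shift) for (dy in -xy_shift:xy_shift) {
      cnt <- 0L
      for (i in seq_len(nrow(qc))) {
        key <- as.character((qc$x[i] + dx) * 10000 + (qc$y[i] + dy))
        td <- tk[key]
        if (!is.na(td) && abs(td - qc$depth[i]) <= z_tol) cnt <- cnt + 1L
      }
      if (cnt > best) best <- cnt
    }
  }
  best
}

# per-voxel DSLT reimplementation (independent of the shift-and-add path)
oracle_dslt <- function(vol, params) {
  d <- dim(vol$data)
  vs <- vol$space$voxel_size_um
  dirs <- colordepth:::dslt_directions(params$n_directions)
  mask <- array(FALSE, d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3])) {
    votes <- 0L
    for (i in seq_len(nrow(dirs))) {
      u <- dirs[i, ]
      step_um <- sqrt(sum((u * vs)^2))
      h <- max(1L, floor(params$line_kernel_length_um / (2 * step_um)))
      ts <- -h:h
      yy <- y + ts * u[2]; xx <- x + ts * u[1]; zz <- z + ts * u[3]
      ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2] & zz >= 1 & zz <= d[3]
      m <- mean(vol$data[cbind(yy[ok], xx[ok], zz[ok])])
      if (vol$data[y, x, z] > m + params$local_offset) votes <- votes + 1L
    }
    mask[y, x, z] <- votes >= params$min_directions_hit
  }
  mask
}

# 6/18/26-neighbour flood fill counting components (independent labeler)
oracle_component_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  count <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      c0 <- cur - 1L
      y <- c0 %% d[1] + 1L; x <- (c0 %/% d[1]) %% d[2] + 1L; z <- c0 %/% (d[1] * d[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        yy <- y + offs[o, 1]; xx <- x + offs[o, 2]; zz <- z + offs[o, 3]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3]) next
        if (!mask[yy, xx, zz] || seen[yy, xx, zz]) next
        seen[yy, xx, zz] <- TRUE
        stack <- c(stack, (zz - 1L) * d[1] * d[2] + (xx - 1L) * d[1] + yy)
      }
    }
  }
  count
}

# brute-force nearest-foreground distance field (um)
oracle_distance_field <- function(fg, vs_xy) {
  ny <- nrow(fg); nx <- ncol(fg)
  out <- matrix(Inf, ny, nx)
  idx <- which(fg)
  if (length(idx) == 0L) return(out)
  fy <- (idx - 1L) %% ny; fx <- (idx - 1L) %/% ny
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    out[y, x] <- sqrt(min(((x - 1L - fx) * vs_xy[1])^2 + ((y - 1L - fy) * vs_xy[2])^2))
  }
  out
}

# all-pairs shape classification oracle on ground-truth depth tables
oracle_shape_classify <- function(em, lm, space, xy_radius, z_um) {
  vs <- space$voxel_size_um
  pos <- 0L; xy_pen <- 0L; z_pen <- 0L
  for (i in seq_len(nrow(em))) {
    d2 <- ((em$x[i] - lm$x) * vs[1])^2 + ((em$y[i] - lm$y) * vs[2])^2
    near <- d2 <= xy_radius^2
    if (!any(near)) xy_pen <- xy_pen + 1L
    else if (min(abs(em$depth[i] - lm$depth[near]) * vs[3]) > z_um) z_pen <- z_pen + 1L
    else pos <- pos + 1L
  }
  list(positive = pos, xy_penalties = xy_pen, z_penalties = z_pen,
       negative = xy_pen + z_pen)
}

# memoized small end-to-end dataset shared across test files
.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- generate_dataset(
      n_em = 5L, n_lines = 3L, seed = 11L, space = mini_space(),
      seg_params = segmentation_params(min_voxels = 50L, min_bbox_extent_um = 8))
  }
  .fixture_cache$tiny
}

tiny_tables <- function() {
  if (is.null(.fixture_cache$tabs)) {
    ds <- tiny_dataset()
    .fixture_cache$tabs <- precompute_all(ds$em_lib, ds$lm_lib, search_params(),
                                          shape_params(), ds$lut)
  }
  .fixture_cache$tabs
}
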