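test_that("depth LUT runs blue to red with distinct, decodable colors", {
  lut2 <- build_depth_lut(2)
  expect_equal(unname(lut2$colors[1, ]), c(0L, 0L, 255L))    # anterior = blue
  expect_equal(unname(lut2$colors[2, ]), c(255L, 0L, 0L))    # posterior = red

  for (n in c(3, 64, 256, 1021)) {
    lut <- build_depth_lut(n)
    expect_equal(nrow(unique(lut$colors)), n)                # bijective
    hsv <- grDevices::rgb2hsv(t(lut$colors))
    expect_true(all(diff(hsv["h", ]) < 0))                   # monotone hue ramp
    decoded <- decode_depth(lut$colors, lut)
    expect_equal(decoded, 0:(n - 1))                         # decode . encode = id
  }
  expect_error(build_depth_lut(1022), "capacity")
  expect_error(build_depth_lut(1), ">= 2")
})

test_that("decode handles background, scaled intensities and junk colors", {
  lut <- build_depth_lut(64)
  expect_true(is.na(decode_depth(c(0, 0, 0), lut)))          # black = background
  expect_error(decode_depth(c(255, 0, 255), lut), "decode")  # magenta: not on ramp
  # intensity-scaled colors decode to the same slice after normalization
  for (k in c(0, 13, 31, 63)) for (f in c(0.3, 0.6, 0.9)) {
    scaled <- round(lut$colors[k + 1, ] * f)
    expect_equal(decode_depth(scaled, lut), k)
  }
})

test_that("encode_volume projects the brightest voxel with shallow tie-break", {
  sp <- flat_space(8, 6, 5)
  lut <- build_depth_lut(5)
  expect_true(all(encode_volume(empty_volume(sp), lut)$pixels == 0))

  vol <- empty_volume(sp)
  vol$data[3, 4, 2] <- 255                    # voxel (x=3, y=2, z=1), 0-based
  cdm <- encode_volume(vol, lut)
  fg <- which(colordepth:::cdm_value(cdm) > 0)
  expect_length(fg, 1L)
  expect_equal(fg, 3L + 3L * 6L)              # (y=3, x=4) 1-based linear index
  expect_equal(unname(cdm$pixels[3, 4, ]), unname(lut$colors[2, ]))

  expect_error(encode_volume(vol, build_depth_lut(7)), "slices")
})

test_that("encoded depth and foreground agree with a per-column scan", {
  sp <- flat_space(12, 10, 6)
  lut <- build_depth_lut(6)
  set.seed(42)
  for (rep in 1:5) {
    vol <- empty_volume(sp)
    vol$data[] <- sample(c(0, 0, 0, 40, 128, 255), length(vol$data), replace = TRUE)
    thr <- 20
    cdm <- encode_volume(vol, lut, intensity_threshold = thr)
    dm <- cdm_depth_map(cdm, lut)
    for (y in 1:10) for (x in 1:12) {
      column <- vol$data[y, x, ]
      if (max(column) > thr) {
        expect_equal(dm[y, x], which.max(column) - 1L)  # which.max = shallowest
      } else {
        expect_true(is.na(dm[y, x]))
      }
    }
  }
})

test_that("skeleton rasterization matches brute-force capsule distances", {
  sp <- flat_space(20, 16, 12)
  nodes <- data.frame(node_id = 1:3, type = c(1L, 3L, 3L),
                      x = c(4, 10, 15), y = c(8, 8, 11), z = c(6, 6, 8),
                      radius = 1, parent_id = c(-1L, 1L, 2L))
  sk <- skeleton(nodes, sp)
  for (r in c(1.5, 3)) {
    vol <- rasterize_skeleton(sk, sp, r)
    # oracle: min distance of each voxel centre to the two segments
    segs <- list(list(a = c(4, 8, 6), b = c(10, 8, 6)),
                 list(a = c(10, 8, 6), b = c(15, 11, 8)))
    for (i in seq(1, 20 * 16 * 12, by = 7)) {   # systematic subsample
      c0 <- i - 1L
      y <- c0 %% 16; x <- (c0 %/% 16) %% 20; z <- c0 %/% (16 * 20)
      p <- c(x + 0.5, y + 0.5, z + 0.5)
      dmin <- min(vapply(segs, function(s)
        sqrt(colordepth:::point_segment_dist2(p[1], p[2], p[3], s$a, s$b)),
        numeric(1)))
      expect_equal(vol$data[y + 1, x + 1, z + 1] > 0, dmin <= r,
                   info = sprintf("voxel (%d,%d,%d) r=%g", x, y, z, r))
    }
  }
})

test_that("rasterization is monotone in radius and clips with a warning", {
  sp <- flat_space(20, 16, 12)
  nodes <- data.frame(node_id = 1:2, type = c(1L, 3L), x = c(5, 12),
                      y = c(8, 8), z = c(6, 6), radius = 1, parent_id = c(-1L, 1L))
  sk <- skeleton(nodes, sp)
  v1 <- rasterize_skeleton(sk, sp, 1.5)
  v2 <- rasterize_skeleton(sk, sp, 3)
  expect_true(all(v2$data[v1$data > 0] > 0))   # enlarging never removes voxels

  out_nodes <- nodes; out_nodes$x <- c(5, 50)  # beyond the 20 um width
  expect_warning(rasterize_skeleton(skeleton(out_nodes, sp), sp, 1.5), "clip")
})

test_that("a single node rasterizes to a sphere of the requested radius", {
  sp <- flat_space(16, 16, 16)
  sk <- skeleton(data.frame(node_id = 1L, type = 1L, x = 8, y = 8, z = 8,
                            radius = 1, parent_id = -1L), sp)
  vol <- rasterize_skeleton(sk, sp, 2.5)
  idx <- which(vol$data > 0, arr.ind = TRUE)
  ctr <- c(8, 8, 8)
  d <- sqrt((idx[, 2] - 0.5 - ctr[1])^2 + (idx[, 1] - 0.5 - ctr[2])^2 +
              (idx[, 3] - 0.5 - ctr[3])^2)
  expect_true(all(d <= 2.5))
  # count must equal the number of voxel centres within the ball
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  inside <- sqrt((g$x + 0.5 - 8)^2 + (g$y + 0.5 - 8)^2 + (g$z + 0.5 - 8)^2) <= 2.5
  expect_equal(nrow(idx), sum(inside))
})

test_that("rotation by 180 degrees preserves rasterized foreground count", {
  sp <- flat_space(24, 24, 12)
  nodes <- data.frame(node_id = 1:3, type = c(1L, 3L, 3L),
                      x = c(6, 12, 17), y = c(6, 12, 15), z = c(4, 6, 8),
                      radius = 1, parent_id = c(-1L, 1L, 2L))
  rot <- nodes
  rot$x <- 24 - nodes$x; rot$y <- 24 - nodes$y   # 180 deg about the centre axis
  n1 <- sum(rasterize_skeleton(skeleton(nodes, sp), sp, 2)$data > 0)
  n2 <- sum(rasterize_skeleton(skeleton(rot, sp), sp, 2)$data > 0)
  expect_equal(n1, n2)
})

test_that("mirroring is an involution and combine unites hemispheres", {
  sp <- flat_space(32, 16, 8)
  lut <- build_depth_lut(8)
  rc <- random_depth_cdm(sp, lut, 30, seed = 9)
  expect_identical(mirror_cdm(mirror_cdm(rc$cdm))$pixels, rc$cdm$pixels)

  # one-sided blob strictly left of midline -> combine doubles the foreground
  left <- make_depth_cdm(data.frame(x = 3:7, y = rep(5, 5), depth = 2:6), sp, lut)
  comb <- combine_mirror(left)
  expect_equal(sum(colordepth:::cdm_value(comb) > 0),
               2L * sum(colordepth:::cdm_value(left) > 0))
  expect_equal(comb$variant, "combined")

  # pixel-symmetric CDM is unchanged by combining
  sym_coords <- data.frame(x = c(3, 28, 10, 21), y = c(5, 5, 9, 9),
                           depth = c(2, 2, 4, 4))
  sym <- make_depth_cdm(sym_coords, sp, lut)
  expect_identical(combine_mirror(sym)$pixels, sym$pixels)
})

test_that("midline crossing detection respects the exclusion band", {
  sp <- flat_space(32, 16, 8)   # midline at x = 16 um
  lut <- build_depth_lut(8)
  both <- make_depth_cdm(data.frame(x = c(4, 27), y = c(5, 5), depth = c(1, 1)), sp, lut)
  onesided <- make_depth_cdm(data.frame(x = c(4, 9), y = c(5, 5), depth = c(1, 1)), sp, lut)
  near <- make_depth_cdm(data.frame(x = c(14, 17), y = c(5, 5), depth = c(1, 1)), sp, lut)
  expect_true(crosses_midline(both))
  expect_false(crosses_midline(onesided))
  expect_false(crosses_midline(near, band_um = 5))  # inside the +/- 5 um band
  expect_true(crosses_midline(near, band_um = 0.2))

  sk <- skeleton(data.frame(node_id = 1:2, type = c(1L, 3L), x = c(4, 27),
                            y = c(5, 5), z = c(1, 1), radius = 1,
                            parent_id = c(-1L, 1L)), sp)
  expect_true(crosses_midline(sk))
})
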