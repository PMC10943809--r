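test_that("uniform volumes segment to an empty mask", {
  sp <- flat_space(16, 16, 16)
  vol <- empty_volume(sp)
  vol$data[] <- 77
  expect_false(any(dslt_segment(vol, segmentation_params(line_kernel_length_um = 6))))
})

test_that("a bright line is recovered and the mask is offset invariant", {
  sp <- flat_space(32, 32, 32)
  params <- segmentation_params(line_kernel_length_um = 8, local_offset = 20,
                                min_directions_hit = 9L)
  vol <- empty_volume(sp)
  vol$data[16, 8:24, 16] <- 200            # 1-voxel-wide line along x
  mask <- dslt_segment(vol, params)
  expect_true(all(mask[16, 8:24, 16]))
  off_line <- mask; off_line[16, 8:24, 16] <- FALSE
  expect_false(any(off_line))              # no background voxels

  lifted <- vol; lifted$data <- vol$data + 50   # constant background shift
  expect_identical(dslt_segment(lifted, params), mask)
})

test_that("kernel longer than the volume is a parameter error", {
  sp <- flat_space(8, 8, 8)
  vol <- empty_volume(sp)
  expect_error(dslt_segment(vol, segmentation_params(line_kernel_length_um = 40)),
               "kernel")
})

test_that("dslt_segment equals the per-voxel oracle on random volumes", {
  params <- segmentation_params(line_kernel_length_um = 6, local_offset = 15,
                                min_directions_hit = 8L)
  for (seed in 1:50) {
    set.seed(seed)
    d <- sample(8:13, 3, replace = TRUE)
    sp <- alignment_space("o", d, c(1, 1, 1))
    vol <- empty_volume(sp)
    vol$data[] <- sample(0:255, length(vol$data), replace = TRUE)
    expect_identical(dslt_segment(vol, params), oracle_dslt(vol, params),
                     info = sprintf("seed %d", seed))
  }
})

test_that("component labeling matches flood-fill counts and is ordered", {
  sp <- flat_space(24, 24, 12)
  mask <- array(FALSE, c(24, 24, 12))
  mask[3:6, 3:6, 3:6] <- TRUE              # blob A: 64 voxels
  mask[15:17, 15:17, 8:9] <- TRUE          # blob B: 18 voxels
  mask[1, 22, 1] <- TRUE                   # single voxel C
  sets <- label_components(mask, sp)
  expect_length(sets, 3L)
  expect_equal(vapply(sets, function(s) s$descriptor$n_voxels, integer(1)),
               c(64L, 18L, 1L))            # size-descending order
  expect_equal(oracle_component_count(mask), 3L)

  # diagonal contact joins under 26-connectivity
  diag_mask <- array(FALSE, c(24, 24, 12))
  diag_mask[5, 5, 5] <- TRUE; diag_mask[6, 6, 6] <- TRUE
  expect_length(label_components(diag_mask, sp), 1L)

  expect_equal(label_components(array(FALSE, c(24, 24, 12)), sp), list())
})

test_that("labeling agrees with the flood-fill oracle on random masks", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    d <- c(14, 12, 10)
    sp <- alignment_space("o", c(d[2], d[1], d[3]), c(1, 1, 1))
    mask <- array(runif(prod(d)) < 0.12, d)
    sets <- label_components(mask, sp)
    expect_equal(length(sets), oracle_component_count(mask))
    expect_equal(sum(vapply(sets, function(s) s$descriptor$n_voxels, integer(1))),
                 sum(mask))
  }
})

test_that("junk filtering drops small sets, caps the count, and is idempotent", {
  sp <- flat_space(32, 32, 16)
  mask <- array(FALSE, c(32, 32, 16))
  mask[2:13, 2:4, 2:4] <- TRUE             # 108 voxels, 12 um long
  mask[20:24, 20:22, 5:7] <- TRUE          # 45 voxels
  mask[30, 30, 10] <- TRUE                 # 1 voxel junk
  sets <- label_components(mask, sp)
  params <- segmentation_params(min_voxels = 10L, min_bbox_extent_um = 3,
                                max_sets_per_channel = 5L)
  kept <- filter_components(sets, params)
  expect_length(kept, 2L)
  expect_identical(filter_components(kept, params), kept)   # idempotent

  capped <- filter_components(sets, segmentation_params(min_voxels = 1L,
                                                        min_bbox_extent_um = 0.5,
                                                        max_sets_per_channel = 1L))
  expect_length(capped, 1L)
  expect_equal(capped[[1]]$descriptor$n_voxels, 108L)

  tiny <- filter_components(sets, segmentation_params(min_voxels = 200L))
  expect_length(tiny, 0L)
})

test_that("per-set CDM foregrounds nest inside the whole-channel CDM", {
  sp <- mini_space()
  lut <- build_depth_lut(sp$shape_xyz[3])
  n1 <- generate_neuron(21, sp, 2)
  n2 <- generate_neuron(22, sp, 2)
  smp <- generate_lm_sample(list(n1, n2), list(c(1L, 2L)), background_level = 8,
                            noise_sd = 4, seed = 5)
  ch <- smp$channels[[1]]
  mask <- dslt_segment(ch, segmentation_params(min_voxels = 50L))
  sets <- filter_components(label_components(mask, sp, ch),
                            segmentation_params(min_voxels = 50L))
  expect_gte(length(sets), 1L)
  cdms <- voxelsets_to_cdms(sets, lut, sp)
  expect_length(cdms, length(sets))
  whole <- encode_volume(ch, lut, intensity_threshold = 20)
  whole_fg <- colordepth:::cdm_value(whole) > 0
  for (cd in cdms) {
    sub_fg <- colordepth:::cdm_value(cd) > 0
    expect_true(all(whole_fg[sub_fg]))     # subset of the channel's foreground
  }
})
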