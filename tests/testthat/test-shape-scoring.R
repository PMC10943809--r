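test_that("the support distance field is exact", {
  sp <- flat_space(24, 20, 8)
  lut <- build_depth_lut(8)
  blank <- make_depth_cdm(data.frame(x = integer(), y = integer(),
                                     depth = integer()), sp, lut)
  expect_true(all(is.infinite(xy_support_distance(blank))))

  rc <- random_depth_cdm(sp, lut, 25, seed = 4)
  d <- xy_support_distance(rc$cdm)
  fg <- colordepth:::cdm_value(rc$cdm) > 0
  expect_true(all(d[fg] == 0))                      # zero on foreground
  oracle <- oracle_distance_field(fg, sp$voxel_size_um[1:2])
  expect_equal(d, oracle, tolerance = 1e-10)
})

test_that("identical CDMs score penalty free", {
  sp <- flat_space(32, 32, 16)
  lut <- build_depth_lut(16)
  rc <- random_depth_cdm(sp, lut, 40, seed = 6)
  r <- shape_penalties(rc$cdm, rc$cdm, shape_params(), lut)
  expect_equal(r$positive, 40L)
  expect_equal(r$negative, 0L)
  expect_equal(shape_score(r), 40)                  # divide by max(negative, 1)
})

test_that("XY displacement beyond the radius penalizes every EM pixel", {
  sp <- alignment_space("iso", c(96L, 64L, 64L), c(1, 1, 1))
  lut <- build_depth_lut(64)
  blob <- data.frame(x = rep(20:24, each = 5), y = rep(20:24, times = 5), depth = 30)
  em <- make_depth_cdm(blob, sp, lut, "em")
  lm20 <- make_depth_cdm(transform(blob, x = x + 20), sp, lut, "lm")  # 20 um away
  r <- shape_penalties(em, lm20, shape_params(), lut)
  expect_equal(r$xy_penalties, nrow(blob))
  expect_equal(r$positive, 0L)
})

test_that("depth mismatch beyond 40 um within XY support is a Z penalty", {
  sp <- alignment_space("iso", c(96L, 64L, 64L), c(1, 1, 1))
  lut <- build_depth_lut(64)
  blob <- data.frame(x = rep(20:24, each = 5), y = rep(20:24, times = 5), depth = 5)
  em <- make_depth_cdm(blob, sp, lut, "em")
  lm_deep <- make_depth_cdm(transform(blob, depth = 55), sp, lut, "lm")  # 50 um deeper
  r <- shape_penalties(em, lm_deep, shape_params(), lut)
  expect_equal(r$z_penalties, nrow(blob))
  expect_equal(r$xy_penalties, 0L)
  expect_equal(r$positive, 0L)
})

test_that("penalty classification agrees with the all-pairs oracle", {
  sp <- alignment_space("iso", c(48L, 48L, 48L), c(1, 1, 1))
  lut <- build_depth_lut(48)
  for (seed in 1:8) {
    em <- random_depth_cdm(sp, lut, 30, seed = 300 + seed, "em")
    lm <- random_depth_cdm(sp, lut, 30, seed = 400 + seed, "lm")
    got <- shape_penalties(em$cdm, lm$cdm, shape_params(), lut)
    want <- oracle_shape_classify(em$coords, lm$coords, sp, 12, 40)
    expect_equal(got$positive, want$positive, info = sprintf("seed %d", seed))
    expect_equal(got$xy_penalties, want$xy_penalties)
    expect_equal(got$z_penalties, want$z_penalties)
  }
})

test_that("scoring is uni-directional and monotone in the XY radius", {
  sp <- alignment_space("iso", c(96L, 64L, 64L), c(1, 1, 1))
  lut <- build_depth_lut(64)
  blob <- data.frame(x = rep(30:33, each = 4), y = rep(30:33, times = 4), depth = 20)
  em <- make_depth_cdm(blob, sp, lut, "em")
  lm <- make_depth_cdm(blob, sp, lut, "lm")
  base <- shape_penalties(em, lm, shape_params(), lut)

  # extra LM-only signal far away: negative unchanged (no LM penalty)
  lm_extra <- make_depth_cdm(rbind(blob, data.frame(x = 70:79, y = 10, depth = 50)),
                             sp, lut, "lm2")
  r2 <- shape_penalties(em, lm_extra, shape_params(), lut)
  expect_equal(r2$negative, base$negative)
  expect_equal(r2$positive, base$positive)

  # extra EM-only signal beyond the radius: negative strictly increases
  em_extra <- make_depth_cdm(rbind(blob, data.frame(x = 70:79, y = 10, depth = 50)),
                             sp, lut, "em2")
  r3 <- shape_penalties(em_extra, lm, shape_params(), lut)
  expect_gt(r3$negative, base$negative)

  # enlarging the radius never increases negative
  prev <- Inf
  for (rad in c(4, 8, 12, 20)) {
    r <- shape_penalties(em_extra, lm, shape_params(xy_radius_um = rad), lut)
    expect_lte(r$negative, prev); prev <- r$negative
  }
})

test_that("ratio score handles the zero-penalty and zero-positive edges", {
  mk <- function(p, n) structure(list(positive = p, negative = n,
                                      xy_penalties = n, z_penalties = 0L),
                                 class = "shape_result")
  expect_equal(shape_score(mk(100L, 50L)), 2)
  expect_equal(shape_score(mk(100L, 0L)), 100)
  expect_equal(shape_score(mk(0L, 7L)), 0)
})

test_that("reranking prefers full coverage over partial high-overlap decoys", {
  sp <- alignment_space("iso", c(96L, 64L, 64L), c(1, 1, 1))
  lut <- build_depth_lut(64)
  # LM pattern: a single neuron trace
  trace <- data.frame(x = 10:50, y = 30, depth = 20)
  lm <- make_depth_cdm(trace, sp, lut, "lm1")
  # true EM neuron: same trace
  em_true <- make_depth_cdm(trace, sp, lut, "true")
  # decoy: overlaps the trace completely (same raw CDM score as the true
  # neuron) but carries a large branch with no LM support
  branch <- data.frame(x = 30, y = c(1:15, 45:64) - 1, depth = 20)
  em_decoy <- make_depth_cdm(rbind(trace, branch), sp, lut, "decoy")

  matches <- search_library(lm, list(em_true, em_decoy), search_params(), lut)
  matches$em_id <- matches$target_id
  matches$em_variant <- matches$target_variant
  matches$lm_id <- "lm1"
  reranked <- rerank_matches(matches,
                             list(true = em_true, decoy = em_decoy),
                             list(lm1 = lm), shape_params(), lut)
  expect_equal(reranked$em_id[1], "true")
  expect_gt(reranked$shape_score[1], reranked$shape_score[2])
  # idempotence: reranking the reranked table changes nothing
  again <- rerank_matches(reranked, list(true = em_true, decoy = em_decoy),
                          list(lm1 = lm), shape_params(), lut)
  expect_equal(again, reranked)
})
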