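test_that("every EM x LM pair is scored once and recorded bidirectionally", {
  sp <- flat_space(32, 32, 16)
  lut <- build_depth_lut(16)
  em <- cdm_library(lapply(1:2, function(i)
    random_depth_cdm(sp, lut, 25, seed = i, sprintf("body_%d", i))$cdm),
    "EM", c("body_1", "body_2"))
  lm <- cdm_library(lapply(1:3, function(i)
    random_depth_cdm(sp, lut, 25, seed = 10 + i, sprintf("lm_%d", i))$cdm),
    "LM", c("line_a", "line_a", "line_b"), sprintf("s%d", 1:3))
  tabs <- precompute_all(em, lm, search_params(), shape_params(), lut)
  expect_equal(tabs$n_pair_evaluations, 6L)          # 2 x 3, no variants
  expect_equal(nrow(tabs$em_to_lm), 6L)
  expect_equal(nrow(tabs$lm_to_em), 6L)
  # both tables come from the same pass: identical pair scores
  key <- function(tb) tb[order(tb$em_id, tb$lm_id),
                         c("em_id", "lm_id", "matched_pixels", "shape_score")]
  expect_equal(key(tabs$em_to_lm), key(tabs$lm_to_em))
  # per-target ranks are 1..n within each direction
  expect_equal(sort(tabs$em_to_lm$rank[tabs$em_to_lm$em_id == "body_1"]), 1:3)
  expect_equal(sort(tabs$lm_to_em$rank[tabs$lm_to_em$lm_id == "lm_1"]), 1:2)
})

test_that("the flip-max rule keeps the better EM variant per pair", {
  sp <- flat_space(32, 16, 8)
  lut <- build_depth_lut(8)
  # one-sided EM neuron plus its combined-mirror variant
  left <- make_depth_cdm(data.frame(x = 2:6, y = 4:8, depth = 1:5), sp, lut, "b1")
  comb <- combine_mirror(left)
  em <- cdm_library(list(left, comb), "EM", "b1")
  # bilateral LM pattern = the combined image itself; one-sided LM = original
  lm <- cdm_library(list(cdm_image(comb$pixels, sp, "lm_bi"),
                         cdm_image(left$pixels, sp, "lm_one")),
                    "LM", c("line_x", "line_y"))
  tabs <- precompute_all(em, lm, search_params(), shape_params(), lut)
  expect_equal(tabs$n_pair_evaluations, 4L)          # 2 variants x 2 LM
  bi <- tabs$lm_to_em[tabs$lm_to_em$lm_id == "lm_bi", ]
  expect_equal(bi$em_variant, "combined")            # bilateral prefers flip
  # reported score equals the max of explicitly recomputed variant scores
  s_orig <- cdm_score(lm$cdm[[1]], left, search_params(), lut)$matched_pixels
  s_comb <- cdm_score(lm$cdm[[1]], comb, search_params(), lut)$matched_pixels
  expect_equal(bi$matched_pixels, max(s_orig, s_comb))
  one <- tabs$lm_to_em[tabs$lm_to_em$lm_id == "lm_one", ]
  s_orig1 <- cdm_score(lm$cdm[[2]], left, search_params(), lut)$matched_pixels
  s_comb1 <- cdm_score(lm$cdm[[2]], comb, search_params(), lut)$matched_pixels
  expect_equal(one$matched_pixels, max(s_orig1, s_comb1))
})

test_that("driver-line grouping caps lines and preserves internal order", {
  # 400 synthetic lines with known scores, several images per line
  set.seed(5)
  n_lines <- 400L
  rows <- do.call(rbind, lapply(seq_len(n_lines), function(l) {
    k <- sample(1:3, 1)
    data.frame(em_id = "b1", em_image_id = "b1", em_variant = "original",
               lm_id = sprintf("img_%03d_%d", l, seq_len(k)),
               lm_line = sprintf("line_%03d", l),
               lm_sample = sprintf("line_%03d_s1", l),
               matched_pixels = sample(10:500, k), dx = 0L, dy = 0L,
               used_flip = FALSE)
  }))
  rows$shape_score <- rows$matched_pixels / 10
  capped <- group_and_cap(tibble::as_tibble(rows), max_lines = 300L)
  expect_equal(length(unique(capped$lm_line)), 300L)  # exactly the cap
  # retained lines are the best 300 by their top representative
  best <- tapply(rows$shape_score, rows$lm_line, max)
  expect_setequal(unique(capped$lm_line),
                  names(sort(best, decreasing = TRUE))[1:300])
  # within a line, scores are non-increasing
  for (l in unique(capped$lm_line)[1:20]) {
    s <- capped$shape_score[capped$lm_line == l]
    expect_true(all(diff(s) <= 0))
  }
  # cap does nothing when lines are fewer than the cap
  few <- group_and_cap(tibble::as_tibble(rows[rows$lm_line < "line_100", ]),
                       max_lines = 300L)
  expect_equal(length(unique(few$lm_line)), 99L)

  one_per <- group_and_cap(tibble::as_tibble(rows), max_lines = 300L,
                           max_per_line = 1L)
  expect_equal(nrow(one_per), 300L)                   # one image per line
  expect_true(all(table(one_per$lm_line) == 1L))
})

test_that("shard_map_reduce is deterministic and conserves work", {
  work <- as.list(1:103)
  f <- function(x) x^2
  serial <- shard_map_reduce(work, f, n_workers = 1L, batch_size = 7L)
  expect_equal(unlist(serial), (1:103)^2)             # conservation + order
  par4 <- shard_map_reduce(work, f, n_workers = 4L, batch_size = 7L)
  expect_identical(serial, par4)
  big_batch <- shard_map_reduce(work, f, n_workers = 2L, batch_size = 1000L)
  expect_identical(serial, big_batch)                 # single batch
  expect_equal(shard_map_reduce(list(), f), list())
})

test_that("a persistently failing batch surfaces its batch id", {
  work <- as.list(1:10)
  f <- function(x) if (x == 7) stop("boom") else x
  expect_error(shard_map_reduce(work, f, n_workers = 1L, batch_size = 3L),
               "batch 3 failed after retry")
  # flaky failure succeeds on the retry
  env <- new.env(); env$tries <- 0L
  flaky <- function(x) {
    if (x == 7) {
      env$tries <- env$tries + 1L
      if (env$tries == 1L) stop("transient")
    }
    x
  }
  expect_equal(unlist(shard_map_reduce(work, flaky, batch_size = 3L)), 1:10)
})

test_that("precompute output is identical for any sharding", {
  ds <- tiny_dataset()
  t1 <- tiny_tables()
  t2 <- precompute_all(ds$em_lib, ds$lm_lib, search_params(), shape_params(),
                       ds$lut, n_workers = 4L, batch_size = 5L)
  expect_equal(t1$em_to_lm, t2$em_to_lm)
  expect_equal(t1$lm_to_em, t2$lm_to_em)
  expect_equal(t1$n_pair_evaluations, t2$n_pair_evaluations)
  # conservation: pair evaluations = sum over EM neurons of variants x |LM|
  n_var <- table(ds$em_lib$neuron_or_line_id)
  expect_equal(t1$n_pair_evaluations, sum(n_var) * nrow(ds$lm_lib))
})
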