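#' CDM library entries
#'
#' A library is a tibble with one row per searchable CDM: the image itself
#' (list column), its modality, the neuron (body id, EM) or driver line id
#' (LM), the biological sample id and channel / voxel-set index. EM entries
#' may carry both an `original` and a `combined` mirror variant of the same
#' neuron; the precompute keeps whichever scores higher per pair.
#'
#' @param cdms List of [cdm_image()]s.
#' @param modality `"EM"` or `"LM"` (scalar or per-entry vector).
#' @param neuron_or_line_id Body id (EM) or driver-line id (LM), per entry.
#' @param sample_id Biological sample id, per entry.
#' @param index Channel or voxel-set index, per entry.
#' @return A tibble of class `cdm_library`.
#' @export
cdm_library <- function(cdms, modality, neuron_or_line_id, sample_id = neuron_or_line_id,
                        index = 1L) {
  n <- length(cdms)
  modality <- rep_len(modality, n)
  if (!all(modality %in% c("EM", "LM"))) abort("modality must be 'EM' or 'LM'")
  tb <- tibble(
    image_id = vapply(cdms, function(c) c$source_id, character(1)),
    variant = vapply(cdms, function(c) c$variant, character(1)),
    modality = modality,
    neuron_or_line_id = as.character(rep_len(neuron_or_line_id, n)),
    sample_id = as.character(rep_len(sample_id, n)),
    index = as.integer(rep_len(index, n)),
    cdm = cdms)
  class(tb) <- c("cdm_library", class(tb))
  tb
}

lib_space <- function(lib) lib$cdm[[1]]$space

#' All-vs-all EM x LM precompute
#'
#' Scores every EM neuron against every LM image once, applies the
#' flip-max rule (for EM neurons carrying both an `original` and a
#' `combined` mirror variant, the higher-scoring variant is kept per pair),
#' re-scores every kept pair with the shape-matching penalty, and records
#' the results in both directions from the single comparison pass: an
#' EM->LM table ranked per EM target and an LM->EM table ranked per LM
#' image. Execution is sharded with [shard_map_reduce()] and is bit-identical
#' for any worker count or batch size.
#'
#' @param em_lib,lm_lib [cdm_library()] tibbles sharing one alignment space.
#' @param search_params A [search_params()].
#' @param shape_params A [shape_params()]; `NULL` skips the shape re-scoring.
#' @param lut The shared [build_depth_lut()].
#' @param n_workers,batch_size Passed to [shard_map_reduce()].
#' @return A list of class `match_tables`: `em_to_lm`, `lm_to_em` (tibbles),
#'   `n_pair_evaluations` (every EM variant x LM image counted once).
#' @export
precompute_all <- function(em_lib, lm_lib, search_params = search_params(),
                           shape_params = shape_params(), lut,
                           n_workers = 1L, batch_size = 64L) {
  if (nrow(em_lib) == 0L || nrow(lm_lib) == 0L) abort("libraries must be non-empty")
  check_same_space(lib_space(em_lib), lib_space(lm_lib), "EM and LM libraries")

  # one work item per (EM neuron, LM image); variants resolved inside
  em_ids <- unique(em_lib$neuron_or_line_id)
  work <- expand.grid(em = em_ids, li = seq_len(nrow(lm_lib)),
                      stringsAsFactors = FALSE)
  work <- work[order(work$em, work$li), ]
  work_list <- purrr::map(seq_len(nrow(work)), function(i)
    list(em = work$em[i], li = work$li[i]))

  n_pairs <- 0L
  score_pair <- function(item) {
    variants <- which(em_lib$neuron_or_line_id == item$em)
    lm_row <- lm_lib[item$li, ]
    best <- NULL
    for (vi in variants) {
      sc <- cdm_score(lm_row$cdm[[1]], em_lib$cdm[[vi]], search_params, lut)
      if (is.null(best) || sc$matched_pixels > best$matched_pixels) {
        best <- c(sc, list(em_variant = em_lib$variant[vi],
                           em_image_id = em_lib$image_id[vi], vi = vi))
      }
    }
    tibble(em_id = item$em, em_image_id = best$em_image_id,
           em_variant = best$em_variant,
           lm_id = lm_row$image_id, lm_line = lm_row$neuron_or_line_id,
           lm_sample = lm_row$sample_id,
           matched_pixels = best$matched_pixels,
           dx = best$best_shift[1], dy = best$best_shift[2],
           used_flip = best$used_flip,
           n_variants = length(variants))
  }
  rows <- shard_map_reduce(work_list, score_pair, n_workers = n_workers,
                           batch_size = batch_size)
  pairs <- dplyr::bind_rows(rows)
  n_pair_evaluations <- sum(pairs$n_variants)
  pairs$n_variants <- NULL

  if (!is.null(shape_params)) {
    em_cdms <- setNames(em_lib$cdm, paste0(em_lib$neuron_or_line_id, "|", em_lib$variant))
    lm_cdms <- setNames(lm_lib$cdm, lm_lib$image_id)
    pairs <- rerank_matches(pairs, em_cdms, lm_cdms, shape_params, lut,
                            threshold = search_params$pixel_intensity_threshold)
    pairs$rank <- NULL
  }

  sortcols <- if (!is.null(shape_params))
    c("shape_score", "matched_pixels") else c("matched_pixels", "matched_pixels")
  rank_within <- function(tb, key) {
    tb <- dplyr::group_by(tb, dplyr::across(dplyr::all_of(key)))
    tb <- dplyr::arrange(tb,
                         dplyr::desc(.data[[sortcols[1]]]),
                         dplyr::desc(.data[[sortcols[2]]]),
                         .data$em_id, .data$lm_id, .by_group = TRUE)
    tb <- dplyr::mutate(tb, rank = dplyr::row_number())
    dplyr::ungroup(tb)
  }
  structure(list(
    em_to_lm = rank_within(pairs, "em_id"),
    lm_to_em = rank_within(pairs, "lm_id"),
    n_pair_evaluations = n_pair_evaluations,
    reranked = !is.null(shape_params)),
    class = "match_tables")
}

#' @export
print.match_tables <- function(x, ...) {
  cat(sprintf("<match_tables> %d pair evaluations, %d EM targets, %d LM images%s\n",
              x$n_pair_evaluations, length(unique(x$em_to_lm$em_id)),
              length(unique(x$lm_to_em$lm_id)),
              if (x$reranked) ", shape-reranked" else ""))
  invisible(x)
}

#' @export
tidy.match_tables <- function(x, direction = c("em_to_lm", "lm_to_em"), ...) {
  direction <- match.arg(direction)
  x[[direction]]
}

#' @export
glance.match_tables <- function(x, ...) {
  tibble(n_pair_evaluations = x$n_pair_evaluations,
         n_em_targets = length(unique(x$em_to_lm$em_id)),
         n_lm_images = length(unique(x$lm_to_em$lm_id)),
         reranked = x$reranked)
}

#' Group matches by driver line and cap the line count
#'
#' LM matches for one EM target are grouped by driver line; lines are ordered
#' by the score of their highest-ranking representative, at most `max_lines`
#' lines are retained (default 300), and within a line at most
#' `max_per_line` representatives are kept (a setting of 1 keeps one image
#' per line, useful when scouting lines for an intersection). Each line's
#' internal score order is preserved.
#'
#' @param matches EM->LM match tibble (rows for one or more EM targets; the
#'   cap applies per EM target).
#' @param max_lines Maximum distinct driver lines per EM target.
#' @param max_per_line Maximum representatives per line (`Inf` = all).
#' @param score_col Column used for ordering; defaults to `shape_score` when
#'   present, else `matched_pixels`.
#' @return The capped tibble, ordered by EM target, then line order, then
#'   within-line score.
#' @export
group_and_cap <- function(matches, max_lines = 300L, max_per_line = Inf,
                          score_col = NULL) {
  score_col <- score_col %||%
    (if ("shape_score" %in% names(matches)) "shape_score" else "matched_pixels")
  capped <- matches |>
    dplyr::group_by(.data$em_id, .data$lm_line) |>
    dplyr::arrange(dplyr::desc(.data[[score_col]]),
                   dplyr::desc(.data$matched_pixels), .data$lm_id,
                   .by_group = TRUE) |>
    dplyr::mutate(within_line_rank = dplyr::row_number(),
                  line_best = .data[[score_col]][1]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$within_line_rank <= max_per_line)
  line_order <- capped |>
    dplyr::distinct(.data$em_id, .data$lm_line, .data$line_best) |>
    dplyr::group_by(.data$em_id) |>
    dplyr::arrange(dplyr::desc(.data$line_best), .data$lm_line, .by_group = TRUE) |>
    dplyr::mutate(line_rank = dplyr::row_number()) |>
    dplyr::ungroup()
  capped |>
    dplyr::inner_join(line_order, by = c("em_id", "lm_line", "line_best")) |>
    dplyr::filter(.data$line_rank <= max_lines) |>
    dplyr::arrange(.data$em_id, .data$line_rank, .data$within_line_rank) |>
    dplyr::select(-"line_best")
}

#' Deterministic sharded map-reduce
#'
#' Partitions a work list into fixed-size batches, maps `fn` over the items
#' of each batch (in parallel over batches when `n_workers > 1`), and
#' reduces by concatenating batch results in batch order — so the output is
#' bit-identical for any `n_workers` and `batch_size`. A failed batch is
#' retried once; a second failure is surfaced with the batch id.
#'
#' @param work A list of work items.
#' @param fn Function applied to each item.
#' @param n_workers Number of worker processes (forked; 1 = serial).
#' @param batch_size Items per batch.
#' @return A list of per-item results in the original work order.
#' @export
shard_map_reduce <- function(work, fn, n_workers = 1L, batch_size = 64L) {
  if (length(work) == 0L) return(list())
  if (batch_size < 1L) abort("batch_size must be >= 1")
  batches <- split(seq_along(work), ceiling(seq_along(work) / batch_size))
  run_batch <- function(bi) {
    idx <- batches[[bi]]
    once <- tryCatch(lapply(work[idx], fn), error = function(e) e)
    if (inherits(once, "error")) {    # retry once, then surface with batch id
      once <- tryCatch(lapply(work[idx], fn), error = function(e)
        abort(sprintf("batch %s failed after retry: %s", bi, conditionMessage(e))))
    }
    once
  }
  results <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(batches), run_batch, mc.cores = n_workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_along(batches), run_batch)
  }
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err)) abort(sprintf("batch %d failed", which(err)[1]))
  unlist(results, recursive = FALSE)
}
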