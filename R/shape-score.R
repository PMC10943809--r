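#' Shape-matching parameters
#'
#' The uni-directional shape re-scoring penalizes EM pixels that lack LM
#' support: an EM foreground pixel with no LM foreground within
#' `xy_radius_um` in the image plane incurs an XY penalty; one with XY
#' support but whose nearest depth among the supporting LM pixels differs by
#' more than `z_mismatch_um` incurs a Z penalty; otherwise it counts as a
#' positive match. LM-only pixels are never penalized, because LM samples
#' typically express in several neurons at once, so extra LM signal is
#' expected — but EM branches missing from the LM pattern are evidence
#' against the match. Both bounds are inclusive (a pixel exactly at the
#' radius still counts as supported).
#'
#' @param xy_radius_um XY support radius in micrometres (default 12).
#' @param z_mismatch_um Maximum tolerated depth difference in micrometres
#'   (default 40).
#' @return A list of class `shape_params`.
#' @export
shape_params <- function(xy_radius_um = 12, z_mismatch_um = 40) {
  if (xy_radius_um <= 0 || z_mismatch_um <= 0)
    abort("shape radii must be > 0")
  structure(list(xy_radius_um = xy_radius_um, z_mismatch_um = z_mismatch_um),
            class = "shape_params")
}

#' Distance field to the nearest LM foreground pixel
#'
#' For every pixel of the image grid, the Euclidean distance (um, using the
#' space's xy voxel size) to the nearest LM foreground pixel; 0 on foreground
#' itself and infinite for a blank image. Uses the exact Euclidean distance
#' transform from EBImage when the xy voxel sizes are isotropic and the
#' package is available, otherwise an exact direct computation against the
#' foreground pixel list.
#'
#' @param lm_cdm A [cdm_image()].
#' @param threshold Foreground brightness cutoff (0..255).
#' @return Numeric ny x nx matrix of distances in micrometres.
#' @export
xy_support_distance <- function(lm_cdm, threshold = 1) {
  fg <- cdm_foreground(lm_cdm, threshold)
  ny <- nrow(fg); nx <- ncol(fg)
  vs <- lm_cdm$space$voxel_size_um
  if (!any(fg)) return(matrix(Inf, ny, nx))
  if (vs[1] == vs[2] && requireNamespace("EBImage", quietly = TRUE)) {
    d_px <- EBImage::distmap(matrix(as.numeric(!fg), ny, nx), metric = "euclidean")
    return(as.matrix(d_px) * vs[1])
  }
  # exact fallback: distance from every pixel to the foreground pixel list
  idx <- which(fg)
  fx <- ((idx - 1L) %/% ny) * vs[1]
  fy <- ((idx - 1L) %% ny) * vs[2]
  px <- rep((seq_len(nx) - 1L) * vs[1], each = ny)
  py <- rep((seq_len(ny) - 1L) * vs[2], times = nx)
  out <- vapply(seq_len(ny * nx), function(i)
    sqrt(min((fx - px[i])^2 + (fy - py[i])^2)), numeric(1))
  matrix(out, ny, nx)
}

#' Classify EM pixels against an LM CDM
#'
#' Applies the shape-matching rule to every EM foreground pixel and tallies
#' positive matches, XY penalties and Z penalties (see [shape_params()]).
#' The classification is per EM pixel; LM-only foreground contributes no
#' penalty (the rule is uni-directional).
#'
#' @param em_cdm,lm_cdm [cdm_image()]s in the same alignment space (EM side
#'   first: its pixels are the ones classified).
#' @param params A [shape_params()].
#' @param lut The shared [build_depth_lut()].
#' @param threshold Foreground brightness cutoff (0..255).
#' @return A list of class `shape_result`: `positive`, `negative`,
#'   `xy_penalties`, `z_penalties` (negative = xy + z penalties).
#' @export
shape_penalties <- function(em_cdm, lm_cdm, params = shape_params(), lut,
                            threshold = 1) {
  check_same_space(em_cdm$space, lm_cdm$space, "EM and LM CDMs")
  sp <- em_cdm$space
  vs <- sp$voxel_size_um
  ny <- sp$shape_xyz[2]; nx <- sp$shape_xyz[1]

  em_fg <- cdm_foreground(em_cdm, threshold)
  em_depth <- cdm_depth_map(em_cdm, lut)
  em_idx <- which(em_fg & !is.na(em_depth))
  n_em <- length(em_idx)
  if (n_em == 0L)
    return(structure(list(positive = 0L, negative = 0L,
                          xy_penalties = 0L, z_penalties = 0L),
                     class = "shape_result"))
  ex <- (em_idx - 1L) %/% ny; ey <- (em_idx - 1L) %% ny
  ed <- em_depth[em_idx]

  lm_fg <- cdm_foreground(lm_cdm, threshold)
  lm_depth <- cdm_depth_map(lm_cdm, lut)
  lm_depth[!lm_fg] <- NA_integer_

  # disc of pixel offsets within the XY radius (inclusive)
  rx <- floor(params$xy_radius_um / vs[1]); ry <- floor(params$xy_radius_um / vs[2])
  disc <- expand.grid(ox = -rx:rx, oy = -ry:ry)
  disc <- disc[(disc$ox * vs[1])^2 + (disc$oy * vs[2])^2 <= params$xy_radius_um^2, ]

  supported <- rep(FALSE, n_em)
  min_zdiff <- rep(Inf, n_em)
  for (i in seq_len(nrow(disc))) {
    tx <- ex + disc$ox[i]; ty <- ey + disc$oy[i]
    ok <- tx >= 0L & tx < nx & ty >= 0L & ty < ny
    if (!any(ok)) next
    ld <- lm_depth[cbind(ty[ok] + 1L, tx[ok] + 1L)]
    has <- !is.na(ld)
    if (!any(has)) next
    w <- which(ok)[has]
    supported[w] <- TRUE
    min_zdiff[w] <- pmin(min_zdiff[w], abs(ed[w] - ld[has]) * vs[3])
  }
  xy_pen <- sum(!supported)
  z_pen <- sum(supported & min_zdiff > params$z_mismatch_um)
  pos <- n_em - xy_pen - z_pen
  structure(list(positive = as.integer(pos), negative = as.integer(xy_pen + z_pen),
                 xy_penalties = as.integer(xy_pen), z_penalties = as.integer(z_pen)),
            class = "shape_result")
}

#' @export
print.shape_result <- function(x, ...) {
  cat(sprintf("<shape_result> positive %d, negative %d (xy %d, z %d), score %.3f\n",
              x$positive, x$negative, x$xy_penalties, x$z_penalties, shape_score(x)))
  invisible(x)
}

#' Ratio shape score
#'
#' The final match score: positive matched pixels divided by the penalty
#' count. A penalty-free match divides by 1 so the score stays finite and
#' order-preserving; a match with no positive pixels scores 0.
#'
#' @param result A `shape_result` from [shape_penalties()].
#' @return Non-negative numeric score.
#' @export
shape_score <- function(result) {
  stopifnot(inherits(result, "shape_result"))
  result$positive / max(result$negative, 1L)
}

#' Re-rank CDM search results by shape score
#'
#' Adds the shape-matching classification to every match record and re-sorts
#' the table by shape score (descending), breaking ties by CDM matched
#' pixels then the pair ids, so the order is a deterministic total order and
#' reranking is idempotent. The EM-side CDM of each record is the one
#' classified; LM-side pixels never penalize.
#'
#' @param matches A tibble of match records carrying `em_id` and `lm_id`
#'   columns (e.g. from [precompute_all()]), or a [search_library()] result
#'   plus a single `em_cdm`/`lm_cdm` role assignment via the lookup lists.
#' @param em_cdms Named list of EM-side [cdm_image()]s, keyed as
#'   `<em_id>` or `<em_id>|<variant>`.
#' @param lm_cdms Named list of LM-side [cdm_image()]s keyed by `lm_id`.
#' @param params A [shape_params()].
#' @param lut The shared [build_depth_lut()].
#' @param threshold Foreground brightness cutoff.
#' @return The input tibble with columns `positive`, `negative`,
#'   `xy_penalties`, `z_penalties`, `shape_score` added, re-sorted, with a
#'   fresh `rank` column.
#' @export
rerank_matches <- function(matches, em_cdms, lm_cdms, params = shape_params(),
                           lut, threshold = 1) {
  if (nrow(matches) == 0L) {
    matches$positive <- integer(); matches$negative <- integer()
    matches$xy_penalties <- integer(); matches$z_penalties <- integer()
    matches$shape_score <- double(); matches$rank <- integer()
    return(matches)
  }
  res <- purrr::map(seq_len(nrow(matches)), function(i) {
    em <- cdm_lookup(em_cdms, matches$em_id[i], matches$em_variant[i])
    lm <- cdm_lookup(lm_cdms, matches$lm_id[i], NULL)
    shape_penalties(em, lm, params, lut, threshold)
  })
  matches$positive <- vapply(res, `[[`, integer(1), "positive")
  matches$negative <- vapply(res, `[[`, integer(1), "negative")
  matches$xy_penalties <- vapply(res, `[[`, integer(1), "xy_penalties")
  matches$z_penalties <- vapply(res, `[[`, integer(1), "z_penalties")
  matches$shape_score <- matches$positive / pmax(matches$negative, 1L)
  matches <- dplyr::arrange(matches, dplyr::desc(.data$shape_score),
                            dplyr::desc(.data$matched_pixels),
                            .data$em_id, .data$lm_id)
  matches$rank <- seq_len(nrow(matches))
  matches
}

# fetch a CDM from a named list by id, optionally id|variant
cdm_lookup <- function(cdms, id, variant) {
  if (!is.null(variant) && !is.na(variant)) {
    key <- paste0(id, "|", variant)
    if (!is.null(cdms[[key]])) return(cdms[[key]])
  }
  out <- cdms[[id]]
  if (is.null(out)) abort(sprintf("no CDM registered under id '%s'", id))
  out
}
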