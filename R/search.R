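#' CDM search parameters
#'
#' Parameters of the pixel-overlap matching kernel. Two overlapping pixels
#' match when both are foreground (brightness at or above
#' `pixel_intensity_threshold`) and their decoded depths differ by at most
#' `z_slice_tolerance` slices. The kernel maximizes the matched-pixel count
#' over xy translations up to `xy_shift_px` in each direction and, when
#' `try_flip` is set, over the mirrored target as well, keeping the higher
#' score.
#'
#' @param xy_shift_px Translation search radius in pixels (default 2).
#' @param z_slice_tolerance Maximum decoded-depth difference in slices
#'   (default 2).
#' @param pixel_intensity_threshold Foreground brightness cutoff, 0..255
#'   (default 32).
#' @param try_flip Also score against the mirrored target (default FALSE;
#'   precompute handles flips through explicit combined-mirror variants).
#' @return A list of class `search_params`.
#' @export
search_params <- function(xy_shift_px = 2L, z_slice_tolerance = 2L,
                          pixel_intensity_threshold = 32, try_flip = FALSE) {
  if (xy_shift_px < 0 || z_slice_tolerance < 0 || pixel_intensity_threshold < 0)
    abort("search parameters must be non-negative")
  structure(list(xy_shift_px = as.integer(xy_shift_px),
                 z_slice_tolerance = as.integer(z_slice_tolerance),
                 pixel_intensity_threshold = pixel_intensity_threshold,
                 try_flip = isTRUE(try_flip)),
            class = "search_params")
}

#' Do two CDM pixels match?
#'
#' The kernel's pixel predicate: both pixels must be foreground and their
#' decoded depths within `z_slice_tolerance` slices of each other.
#'
#' @param c1,c2 Integer RGB triples (0..255).
#' @param params A [search_params()].
#' @param lut The [build_depth_lut()] the pixels were encoded with.
#' @return Logical scalar.
#' @export
pixels_match <- function(c1, c2, params, lut) {
  v1 <- max(c1); v2 <- max(c2)
  if (v1 < params$pixel_intensity_threshold || v2 < params$pixel_intensity_threshold)
    return(FALSE)
  d1 <- decode_depth(c1, lut); d2 <- decode_depth(c2, lut)
  if (is.na(d1) || is.na(d2)) return(FALSE)
  abs(d1 - d2) <= params$z_slice_tolerance
}

# precomputed sparse view of a CDM: foreground pixel coords (0-based) and
# depths, plus the full depth map for O(1) shifted lookup
cdm_sparse <- function(cdm, params, lut) {
  fgmask <- cdm_value(cdm) >= params$pixel_intensity_threshold
  depth <- cdm_depth_map(cdm, lut)
  depth[!fgmask | is.na(depth)] <- NA_integer_
  idx <- which(fgmask & !is.na(depth))
  ny <- dim(cdm$pixels)[1]
  list(ny = ny, nx = dim(cdm$pixels)[2],
       y = (idx - 1L) %% ny, x = (idx - 1L) %/% ny,
       depth_at_fg = depth[idx], depth = depth)
}

match_count_sparse <- function(qs, ts, dx, dy, tol) {
  tx <- qs$x + dx; ty <- qs$y + dy
  ok <- tx >= 0L & tx < ts$nx & ty >= 0L & ty < ts$ny
  if (!any(ok)) return(0L)
  td <- ts$depth[cbind(ty[ok] + 1L, tx[ok] + 1L)]
  sum(!is.na(td) & abs(td - qs$depth_at_fg[ok]) <= tol)
}

#' Count matching pixels at a fixed translation
#'
#' Counts query foreground pixels whose target pixel at
#' `(x + dx, y + dy)` satisfies [pixels_match()]; pairs falling outside the
#' target never match.
#'
#' @param query,target [cdm_image()]s in the same alignment space.
#' @param dx,dy Integer translation applied to the query positions.
#' @param params A [search_params()].
#' @param lut The shared [build_depth_lut()].
#' @return Integer matched-pixel count.
#' @export
match_count <- function(query, target, dx = 0L, dy = 0L,
                        params = search_params(), lut) {
  check_same_space(query$space, target$space, "query and target CDMs")
  qs <- cdm_sparse(query, params, lut)
  ts <- cdm_sparse(target, params, lut)
  match_count_sparse(qs, ts, as.integer(dx), as.integer(dy), params$z_slice_tolerance)
}

#' Score a CDM pair
#'
#' The full matching kernel: the maximum of [match_count()] over all
#' translations in the `xy_shift_px` square and, if `try_flip`, over the
#' mirrored target, keeping the higher score. Ties are broken
#' deterministically toward the smaller shift magnitude (then smaller dx,
#' dy), and toward the original over the flipped target.
#'
#' @inheritParams match_count
#' @return A list of class `match_score`: `matched_pixels`, `best_shift`
#'   (dx, dy), `used_flip`.
#' @export
cdm_score <- function(query, target, params = search_params(), lut) {
  check_same_space(query$space, target$space, "query and target CDMs")
  qs <- cdm_sparse(query, params, lut)
  r <- params$xy_shift_px
  shifts <- expand.grid(dx = -r:r, dy = -r:r)
  shifts <- shifts[order(shifts$dx^2 + shifts$dy^2, shifts$dx, shifts$dy), ]
  best <- list(matched_pixels = -1L, best_shift = c(0L, 0L), used_flip = FALSE)
  variants <- list(list(flip = FALSE, ts = cdm_sparse(target, params, lut)))
  if (params$try_flip)
    variants <- c(variants, list(list(flip = TRUE,
                                      ts = cdm_sparse(mirror_cdm(target), params, lut))))
  for (v in variants) {
    for (i in seq_len(nrow(shifts))) {
      m <- match_count_sparse(qs, v$ts, shifts$dx[i], shifts$dy[i],
                              params$z_slice_tolerance)
      if (m > best$matched_pixels) {   # strict '>' keeps first = preferred order
        best <- list(matched_pixels = m,
                     best_shift = c(shifts$dx[i], shifts$dy[i]),
                     used_flip = v$flip)
      }
    }
  }
  best$matched_pixels <- as.integer(max(best$matched_pixels, 0L))
  structure(best, class = "match_score")
}

#' Search a CDM library
#'
#' Scores a query CDM against every library image with [cdm_score()] and
#' returns one row per target, ranked by matched pixels (descending), ties
#' broken by target source id for a deterministic total order. The
#' normalized score divides matched pixels by the query's foreground count.
#'
#' @param query A [cdm_image()].
#' @param library A list of [cdm_image()]s sharing the query's space.
#' @param params A [search_params()].
#' @param lut The shared [build_depth_lut()].
#' @return A tibble with columns `target_id`, `target_variant`,
#'   `matched_pixels`, `dx`, `dy`, `used_flip`, `normalized_score`, `rank`.
#' @export
search_library <- function(query, library, params = search_params(), lut) {
  if (length(library) == 0L)
    return(tibble(target_id = character(), target_variant = character(),
                  matched_pixels = integer(), dx = integer(), dy = integer(),
                  used_flip = logical(), normalized_score = double(),
                  rank = integer()))
  qs <- cdm_sparse(query, params, lut)
  qfg <- length(qs$x)
  rows <- purrr::map_dfr(library, function(tgt) {
    sc <- cdm_score(query, tgt, params, lut)
    tibble(target_id = tgt$source_id, target_variant = tgt$variant,
           matched_pixels = sc$matched_pixels,
           dx = sc$best_shift[1], dy = sc$best_shift[2], used_flip = sc$used_flip,
           normalized_score = sc$matched_pixels / max(qfg, 1L))
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$matched_pixels),
                         .data$target_id, .data$target_variant)
  rows$rank <- seq_len(nrow(rows))
  rows
}
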