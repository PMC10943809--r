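#' Plot a CDM image
#'
#' Renders the RGB pixels with [ggplot2::annotation_raster()] on the image's
#' pixel coordinate frame (origin top-left, x rightward), with a dashed line
#' at the alignment-space midline.
#'
#' @param object A [cdm_image()].
#' @param show_midline Draw the midline guide.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cdm_image <- function(object, show_midline = TRUE, ...) {
  ny <- dim(object$pixels)[1]; nx <- dim(object$pixels)[2]
  rast <- array(object$pixels / 255, dim(object$pixels))
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = nx, ymin = -ny, ymax = 0) +
    ggplot2::xlim(0, nx) + ggplot2::ylim(-ny, 0) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("%s (%s)", object$source_id, object$variant),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (show_midline) {
    mid <- object$space$midline_x_um / object$space$voxel_size_um[1]
    p <- p + ggplot2::geom_vline(xintercept = mid, linetype = "dashed",
                                 colour = "grey60")
  }
  p
}

#' Plot a ranked match table
#'
#' Bar chart of the top matches for one query/target, colored by driver line
#' (when present), using the shape score if the table carries one and the
#' raw matched-pixel count otherwise.
#'
#' @param matches A match tibble from [search_library()], [precompute_all()]
#'   tables or [group_and_cap()].
#' @param top_n How many top rows to show.
#' @return A ggplot object.
#' @export
plot_matches <- function(matches, top_n = 20L) {
  score_col <- if ("shape_score" %in% names(matches)) "shape_score" else "matched_pixels"
  id_col <- if ("target_id" %in% names(matches)) "target_id" else "em_id"
  df <- utils::head(matches[order(-matches[[score_col]]), ], top_n)
  df$label <- stats::reorder(df[[id_col]], df[[score_col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data[[score_col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = score_col) +
    ggplot2::theme_minimal()
}
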