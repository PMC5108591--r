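# ggplot2 views of the main result types. Rasters are melted to long
# tibbles; plots stay light enough for QC at the command line.

raster_to_tibble <- function(m, value_name = "intensity") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m))
}

#' Plot a frame channel
#'
#' @param frame a `myo_frame`.
#' @param channel channel name to display.
#' @return A ggplot object.
#' @export
plot_frame <- function(frame, channel = "cyto") {
  channels <- if (inherits(frame, "myo_frame")) frame$channels else frame
  d <- raster_to_tibble(channels[[channel]])
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = channel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_frame
#' @param object a `myo_scene`.
#' @param ... passed to [plot_frame()].
#' @export
autoplot.myo_scene <- function(object, ...) {
  plot_frame(object$frame, ...) +
    ggplot2::geom_point(
      data = object$nuclei,
      ggplot2::aes(x = .data$col + 1, y = .data$row + 1),
      inherit.aes = FALSE, colour = "red", size = 0.4)
}

#' QC overlay of a segmentation
#'
#' Cell territories coloured by label with nucleus outlines, the annotated
#' view used to assess whether overlapping cytoplasm was segregated
#' correctly.
#'
#' @param object a `myo_segmentation`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.myo_segmentation <- function(object, ...) {
  d <- raster_to_tibble(object$cell_labels, "label")
  d <- dplyr::filter(d, .data$label > 0)
  nd <- raster_to_tibble(object$nucleus_labels, "nucleus")
  nd <- dplyr::filter(nd, .data$nucleus > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$label %% 12))) +
    ggplot2::geom_raster(data = nd, fill = "black", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-condition fitted ratios of an effect report
#'
#' @param object a `myo_effect_report`.
#' @param ... unused.
#' @return A ggplot object with fitted response-scale values and their
#'   Wald intervals.
#' @export
autoplot.myo_effect_report <- function(object, ...) {
  d <- object$conditions
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$fitted)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.2) +
    ggplot2::labs(y = if (object$link == "logit") "fitted probability"
                  else "fitted rate", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Dose-response view of per-frame assay summaries
#'
#' @param summaries per-frame tibble with `dose`, `fusion_index` and
#'   `condition` columns (e.g. from [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$dose, .data$fusion_index,
                               colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "dose", y = "fusion index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
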