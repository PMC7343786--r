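#' Plot the distribution of selected features by group
#'
#' Boxplots of one or more synchronisation features split by the cohort
#' label, the standard way of eyeballing the group differences probed by
#' the Wilcoxon comparisons.
#'
#' @param table Cohort tibble with feature columns and a label column.
#' @param features Character vector of feature columns to show; defaults to
#'   the mean phase shifts of the three cross-correlation types.
#' @param label_col Name of the label column.
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(table,
                                       features = c("mean_CC1", "mean_CC2", "mean_CC3"),
                                       label_col = "label") {
  features <- intersect(features, names(table))
  df <- table |>
    select(dplyr::all_of(c(label_col, features))) |>
    tidyr::pivot_longer(-dplyr::all_of(label_col),
                        names_to = "feature", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data[[label_col]], .data$value,
                                   fill = .data[[label_col]])) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "feature value") +
    ggplot2::theme_minimal()
}

#' Display one frame of an image sequence with optional contours
#'
#' @param seq An [image_sequence()].
#' @param frame Frame number.
#' @param contours Optional contour tibble (`roi, row, col`) to overlay.
#' @return A ggplot object (raster in image orientation: row 1 on top).
#' @export
plot_frame <- function(seq, frame = 1, contours = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  m <- seq$frames[, , frame]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m))) |>
    mutate(intensity = as.vector(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitudinal (px)", y = "radial (px)") +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none")
  if (!is.null(contours)) {
    p <- p + ggplot2::geom_path(data = contours,
                                ggplot2::aes(colour = .data$roi), linewidth = 0.4)
  }
  p
}
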