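# File formats: image sequences as multi-page 8-bit grayscale TIFF;
# contours, trajectories and feature tables as CSV. On disk, pixel
# coordinates and frame numbers are 0-based (row = radial axis increasing
# downward); in R everything is 1-based.

#' Write an image sequence as multi-page 8-bit TIFF
#' @param seq An [image_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  pages <- purrr::map(seq_len(n_frames(seq)), function(f) {
    clamp(round(seq$frames[, , f]), 0, 255) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a multi-page TIFF as an image sequence
#' @param path TIFF file.
#' @param frame_rate Frames per second of the recording.
#' @param spacing Pixels per mm.
#' @return An [image_sequence()] with intensities in 0-255.
#' @export
read_image_sequence <- function(path, frame_rate = 25, spacing = 12) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * 255
  })
  image_sequence(pages, frame_rate = frame_rate, spacing = spacing)
}

#' Write ROI contours as CSV (0-based coordinates)
#' @param contours Tibble `roi, pixel, row, col`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  out <- mutate(contours, pixel = .data$pixel - 1L,
                row = .data$row - 1, col = .data$col - 1)
  write.csv(out[c("roi", "pixel", "row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' Read ROI contours from CSV (0-based coordinates on disk)
#' @param path CSV path.
#' @return Tibble `roi, pixel, row, col`, 1-based.
#' @export
read_contours <- function(path) {
  as_tibble(read.csv(path)) |>
    mutate(pixel = .data$pixel + 1L, row = .data$row + 1, col = .data$col + 1)
}

#' Write pixel trajectories as CSV (0-based coordinates and frames)
#' @param traj Tibble `roi, pixel, frame, row, col`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  out <- mutate(traj, pixel = .data$pixel - 1L, frame = .data$frame - 1L,
                row = .data$row - 1, col = .data$col - 1)
  write.csv(out[c("roi", "pixel", "frame", "row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' Read pixel trajectories from CSV
#' @param path CSV path (0-based on disk).
#' @return Tibble `roi, pixel, frame, row, col`, 1-based.
#' @export
read_trajectories <- function(path) {
  as_tibble(read.csv(path)) |>
    mutate(pixel = .data$pixel + 1L, frame = .data$frame + 1L,
           row = .data$row + 1, col = .data$col + 1)
}

#' Write a plaque feature table as CSV
#' @param features Tibble with the 24 feature columns and any label columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a plaque feature table from CSV
#' @param path CSV path.
#' @return Tibble.
#' @export
read_features <- function(path) {
  out <- as_tibble(read.csv(path))
  if ("label" %in% names(out)) out$label <- factor(out$label)
  out
}

#' Write a leave-one-out evaluation report as JSON
#' @param eval A `plq_eval` from [evaluate_loocv()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(eval, path) {
  stopifnot(inherits(eval, "plq_eval"))
  jsonlite::write_json(
    list(metrics = as.list(eval$metrics),
         predictions = eval$predictions,
         settings = eval$settings[c("positive", "seed", "pca_variance",
                                    "balance", "tune")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
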