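#' B-mode image sequence container
#'
#' A grayscale frame stack with its acquisition metadata. Frames are stored
#' as a rows x cols x frames numeric array with intensities in `[0, 255]`;
#' rows are the radial (depth) axis increasing downward, columns the
#' longitudinal axis.
#'
#' @param frames 3-D numeric array `[rows, cols, frames]`, or a list of
#'   equally sized matrices.
#' @param frame_rate Frames per second (default 25).
#' @param spacing Spatial sampling in pixels per mm (default 12).
#' @return An `image_sequence` object.
#' @export
image_sequence <- function(frames, frame_rate = 25, spacing = 12) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop_plq("all frames must share one shape", "invalid_sequence")
    }
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[3] < 2L) {
    stop_plq("an image sequence needs a rows x cols x frames array with >= 2 frames",
             "invalid_sequence")
  }
  if (!is_scalar_number(frame_rate) || frame_rate <= 0 ||
      !is_scalar_number(spacing) || spacing <= 0) {
    stop_plq("`frame_rate` and `spacing` must be positive numbers", "invalid_sequence")
  }
  structure(list(frames = frames, frame_rate = frame_rate, spacing = spacing),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence: %d x %d px, %d frames @ %g fps, %g px/mm>\n",
              d[1], d[2], d[3], x$frame_rate, x$spacing))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]
frame_dim <- function(seq) dim(seq$frames)[1:2]
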