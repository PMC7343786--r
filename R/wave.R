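#' Displacement waveform
#'
#' A `plq_wave` is a numeric vector of per-frame values (displacements in mm,
#' a wall diameter in mm, or pixel positions when `units = "px"`) carrying its
#' sampling rate and a kind tag, so that filtering, windowing and
#' cross-correlation always know the time base.
#'
#' @param values Numeric vector, one value per frame; length at least 2, all
#'   finite.
#' @param frame_rate Sampling rate in frames per second.
#' @param kind Waveform kind, e.g. `"wall_diameter"`, `"PTS_radial"`,
#'   `"PBS_longitudinal"`, `"plaque_radial_distance"`.
#' @param units Physical units of `values` (`"mm"` or `"px"`).
#'
#' @return A `plq_wave` object.
#' @examples
#' w <- wave(sin(2 * pi * 1.2 * seq(0, 4, by = 1 / 25)), frame_rate = 25)
#' frame_rate(w)
#' @export
wave <- function(values, frame_rate, kind = "generic", units = "mm") {
  if (!is.numeric(values) || length(values) < 2L) {
    stop_plq("a waveform needs at least 2 numeric values", "invalid_wave")
  }
  if (!all(is.finite(values))) {
    stop_plq("waveform values must all be finite", "invalid_wave")
  }
  if (!is_scalar_number(frame_rate) || frame_rate <= 0) {
    stop_plq("`frame_rate` must be a positive number", "invalid_wave")
  }
  structure(as.numeric(values),
            frame_rate = frame_rate, kind = kind, units = units,
            class = "plq_wave")
}

#' Sampling rate of a waveform
#' @param x A [wave()] object.
#' @return Frames per second.
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

wave_kind <- function(x) attr(x, "kind")

# Rebuild a wave with new values but the same metadata.
rewave <- function(values, template, kind = wave_kind(template)) {
  wave(values, frame_rate(template), kind = kind, units = attr(template, "units"))
}

#' @export
print.plq_wave <- function(x, ...) {
  cat(sprintf("<plq_wave: %s, %d frames @ %g fps, %s>\n",
              wave_kind(x), length(x), frame_rate(x), attr(x, "units")))
  print(as.numeric(utils::head(x, 8)))
  if (length(x) > 8) cat("...\n")
  invisible(x)
}

#' @export
as_tibble.plq_wave <- function(x, ...) {
  tibble(frame = seq_along(x),
         time = (seq_along(x) - 1) / frame_rate(x),
         value = as.numeric(x))
}

#' @export
autoplot.plq_wave <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s (%s)", wave_kind(object), attr(object, "units")),
                  title = wave_kind(object)) +
    ggplot2::theme_minimal()
}
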