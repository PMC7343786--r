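#' Trim plaque edge pixels from a trajectory
#'
#' Removes the first and last `n_trim` pixels of a PTS or PBS trajectory so
#' that only plaque tissue, and no adjacent normal wall, enters the
#' analysis. The default of 25 pixels per side matches the margin used for
#' clinical annotations at 12 px/mm.
#'
#' @param traj Trajectory tibble (`roi, pixel, frame, row, col`).
#' @param n_trim Pixels removed from each end (by pixel index order).
#' @return The trimmed trajectory tibble, pixel order preserved.
#' @export
trim_plaque_edges <- function(traj, n_trim = 25) {
  if (!is_scalar_number(n_trim) || n_trim < 0) {
    stop_plq("`n_trim` must be a non-negative count", "invalid_trim")
  }
  px <- sort(unique(traj$pixel))
  if (length(px) <= 2 * n_trim) {
    stop_plq(sprintf("plaque too short: %d pixels cannot lose %d from each edge",
                     length(px), n_trim), "too_short_plaque")
  }
  keep <- px[seq.int(n_trim + 1, length(px) - n_trim)]
  filter(traj, .data$pixel %in% keep)
}

# First-frame column of each trajectory pixel, rounded: the key used for
# vertical pairing of interfaces.
anchor_columns <- function(traj) {
  f1 <- min(traj$frame)
  traj |>
    filter(.data$frame == f1) |>
    mutate(column = round(.data$col)) |>
    select("pixel", "column")
}

# Per-frame radial (row) series of each pixel, in mm, wide by pixel.
radial_series <- function(traj, spacing) {
  traj |> arrange(.data$pixel, .data$frame) |>
    group_by(.data$pixel) |>
    summarise(values = list(.data$row / spacing), .groups = "drop")
}

longitudinal_series <- function(traj, spacing) {
  traj |> arrange(.data$pixel, .data$frame) |>
    group_by(.data$pixel) |>
    summarise(values = list(.data$col / spacing), .groups = "drop")
}

# Vertically aligned pixel pairs of two trajectories: same rounded
# first-frame column; columns lacking a partner are dropped.
vertical_pairs <- function(traj_a, traj_b) {
  ca <- anchor_columns(traj_a) |> distinct(.data$column, .keep_all = TRUE)
  cb <- anchor_columns(traj_b) |> distinct(.data$column, .keep_all = TRUE)
  dplyr::inner_join(ca, cb, by = "column", suffix = c("_a", "_b"))
}

# Fraction of periodogram power concentrated at the in-band peak +/- 1 bin:
# the cyclicity score used to pick the most clearly cyclic diameter pair.
cyclicity_score <- function(values, fs, band) {
  if (stats::sd(values) < 1e-12) return(NA_real_)
  pg <- periodogram(values, fs)
  tot <- sum(pg$power)
  if (tot <= 0) return(NA_real_)
  in_band <- which(pg$frequency >= band[1] & pg$frequency <= band[2])
  if (length(in_band) == 0) return(NA_real_)
  pk <- in_band[which.max(pg$power[in_band])]
  sel <- intersect((pk - 1):(pk + 1), seq_len(nrow(pg)))
  sum(pg$power[sel]) / tot
}

#' Wall diameter waveform
#'
#' Forms, for every vertically aligned AWL-PWL pixel pair, the per-frame
#' radial distance (in mm), and returns the single pair showing the most
#' clearly cyclic motion: the pair maximising the fraction of spectral power
#' concentrated at its dominant in-band frequency.
#'
#' @param awl,pwl Trajectory tibbles for the anterior and posterior
#'   wall-lumen interfaces.
#' @param frame_rate Frames per second.
#' @param spacing Pixels per mm.
#' @param band Frequency band (Hz) searched for cardiac periodicity.
#' @return A [wave()] of kind `"wall_diameter"` with attributes `column`
#'   (the selected column) and `cyclicity` (its score).
#' @export
wall_diameter <- function(awl, pwl, frame_rate, spacing = 12, band = c(0.6, 3)) {
  pairs <- vertical_pairs(awl, pwl)
  if (nrow(pairs) == 0) {
    stop_plq("AWL and PWL share no vertically aligned pixel pairs", "no_pairs")
  }
  sa <- radial_series(awl, spacing)
  sb <- radial_series(pwl, spacing)
  diam <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- sa$values[[match(pairs$pixel_a[i], sa$pixel)]]
    b <- sb$values[[match(pairs$pixel_b[i], sb$pixel)]]
    abs(b - a)
  })
  scores <- map_dbl(diam, cyclicity_score, fs = frame_rate, band = band)
  if (all(is.na(scores))) {
    stop_plq("no cyclic wall motion detected (all candidate diameters constant)",
             "no_cyclic_motion")
  }
  best <- which.max(scores)
  w <- wave(diam[[best]], frame_rate, kind = "wall_diameter")
  attr(w, "column") <- pairs$column[best]
  attr(w, "cyclicity") <- scores[best]
  w
}

#' Plaque radial distance waveforms
#'
#' One series per vertically aligned PTS-PBS pixel pair: the per-frame
#' absolute radial distance between top and bottom plaque surfaces (mm).
#' This is the plaque radial deformation correlated against the wall
#' diameter (cross-correlation type 1).
#'
#' @param pts,pbs Trimmed PTS and PBS trajectory tibbles.
#' @param frame_rate Frames per second.
#' @param spacing Pixels per mm.
#' @return Named list of [wave()] objects, one per pair, named by column.
#' @export
plaque_radial_distance <- function(pts, pbs, frame_rate, spacing = 12) {
  pairs <- vertical_pairs(pts, pbs)
  if (nrow(pairs) == 0) {
    stop_plq("PTS and PBS share no vertically aligned pixel pairs", "no_pairs")
  }
  st <- radial_series(pts, spacing)
  sb <- radial_series(pbs, spacing)
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- st$values[[match(pairs$pixel_a[i], st$pixel)]]
    b <- sb$values[[match(pairs$pixel_b[i], sb$pixel)]]
    wave(abs(a - b), frame_rate, kind = "plaque_radial_distance")
  })
  names(out) <- pairs$column
  out
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero-phase), so filtering does not bias cross-correlation lags. The
#' 0.6 Hz default removes baseline drift while leaving heart rates above
#' roughly 40 bpm untouched.
#'
#' @param ts A [wave()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @return The filtered [wave()]; DC is removed.
#' @export
highpass <- function(ts, cutoff = 0.6, order = 4) {
  fs <- frame_rate(ts)
  if (cutoff >= fs / 2) {
    stop_plq("cutoff must be below the Nyquist frequency", "invalid_filter")
  }
  if (length(ts) <= 3 * (2 * order + 1)) {
    stop_plq("series shorter than the filter warm-up length", "too_short_series")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  rewave(filtfilt_ic(bf$b, bf$a, as.numeric(ts)), ts)
}

# Zero-phase forward-backward IIR filtering with odd-symmetric end padding
# and steady-state initial conditions (Gustafsson-style start-up), which
# keeps edge transients far smaller than naive double filtering.
filtfilt_ic <- function(b, a, x) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  nfact <- 3 * (nfilt - 1)
  n <- length(x)
  if (n <= nfact) {
    stop_plq("series shorter than the filter warm-up length", "too_short_series")
  }
  # steady-state filter state for a unit-step input
  A <- diag(nfilt - 1)
  A[, 1] <- A[, 1] + a[-1]
  if (nfilt > 2) {
    A[seq_len(nfilt - 2), -1] <- A[seq_len(nfilt - 2), -1] - diag(nfilt - 2)
  }
  zi <- solve(A, b[-1] - b[1] * a[-1])
  xp <- c(2 * x[1] - rev(x[2:(nfact + 1)]), x,
          2 * x[n] - rev(x[(n - nfact):(n - 1)]))
  run <- function(v, z0) {
    y <- numeric(length(v)); z <- z0
    for (i in seq_along(v)) {
      y[i] <- b[1] * v[i] + z[1]
      z <- c(z[-1], 0) + b[-1] * v[i] - a[-1] * y[i]
    }
    y
  }
  y <- run(xp, zi * xp[1])
  y <- rev(run(rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + n)]
}

#' Dominant cardiac frequency and average cycle window
#'
#' Finds the in-band periodogram peak of a waveform (normally the wall
#' diameter) and derives the average cardiac cycle window used to confine
#' the signals before cross-correlation: `round(frame_rate / f0)` samples
#' starting at the diameter minimum (end-diastole) within the first cycle.
#'
#' @param ts A [wave()].
#' @param band Search band in Hz; the default 0.6-3 Hz covers roughly
#'   36-180 bpm.
#' @param peak_factor The in-band peak must exceed `peak_factor` times the
#'   median periodogram ordinate, otherwise no dominant frequency is
#'   declared.
#' @param warmup Filter warm-up to skip, in seconds, before the window may
#'   start: high-pass transients decay over roughly one cutoff period, so
#'   the default matches the 0.6 Hz drift filter. Shorter recordings fall
#'   back to the latest start that still fits a window.
#' @return A `cycle_window` list: `f0` (Hz), `window_length` (samples),
#'   `start` (index).
#' @export
dominant_frequency <- function(ts, band = c(0.6, 3), peak_factor = 10,
                               warmup = 1 / 0.6) {
  fs <- frame_rate(ts)
  n <- length(ts)
  if (n < fs / band[1]) {
    stop_plq("series shorter than one period at the band minimum", "too_short_series")
  }
  pg <- periodogram(as.numeric(ts), fs)
  in_band <- which(pg$frequency >= band[1] & pg$frequency <= band[2])
  if (length(in_band) == 0) {
    stop_plq("no periodogram ordinates inside the search band", "no_dominant_frequency")
  }
  pk <- in_band[which.max(pg$power[in_band])]
  if (pg$power[pk] < peak_factor * median(pg$power) || pg$power[pk] <= 0) {
    stop_plq("no in-band power above the noise floor", "no_dominant_frequency")
  }
  f0 <- pg$frequency[pk]
  L <- round(fs / f0)
  if (L > n) {
    stop_plq("cycle window longer than the recording", "no_dominant_frequency")
  }
  # window starts at a diameter minimum (end-diastole) within one cycle
  # after the filter warm-up, or as late as the recording allows
  w0 <- min(round(warmup * fs), n - 2 * L + 1)
  w0 <- max(w0, 0)
  search <- seq.int(w0 + 1, min(w0 + L, n - L + 1))
  start <- search[which.min(as.numeric(ts)[search])]
  structure(list(f0 = f0, window_length = as.integer(L), start = as.integer(start)),
            class = "cycle_window")
}

#' @export
print.cycle_window <- function(x, ...) {
  cat(sprintf("<cycle_window: f0 = %.3g Hz, %d samples from index %d>\n",
              x$f0, x$window_length, x$start))
  invisible(x)
}

#' Truncate a waveform to one average cycle window
#'
#' @param ts A [wave()].
#' @param cw A `cycle_window` from [dominant_frequency()].
#' @return The windowed [wave()] of length `cw$window_length`.
#' @export
window_wave <- function(ts, cw) {
  idx <- seq.int(cw$start, cw$start + cw$window_length - 1)
  if (max(idx) > length(ts)) {
    stop_plq("cycle window exceeds the series length", "invalid_window")
  }
  rewave(as.numeric(ts)[idx], ts)
}
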