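cc_feature_names <- function() {
  stats <- c("sp", "max", "min", "mean", "median", "stdev", "skewness", "kurtosis")
  as.vector(vapply(c("CC1", "CC2", "CC3"),
                   function(cc) paste0(stats, "_", cc), character(8)))
}

# Filter + window one wave against a prepared cycle window.
prep_wave <- function(w, cw, cutoff, order) {
  window_wave(highpass(w, cutoff = cutoff, order = order), cw)
}

#' Per-pair cross-correlation measurements of a plaque
#'
#' Runs the full synchronisation measurement for one plaque: every waveform
#' is high-pass filtered (zero-phase Butterworth), confined to the average
#' cardiac cycle window estimated from the wall-diameter waveform, and
#' cross-correlated. Three correlation types are formed:
#' \describe{
#'   \item{CC1}{each plaque radial-distance series (|PTS - PBS| radial,
#'     plaque radial deformation) against the wall-diameter series;}
#'   \item{CC2}{radial displacements of vertically paired PTS and PBS
#'     pixels;}
#'   \item{CC3}{longitudinal displacements of the same pairs.}
#' }
#'
#' @param wall A wall-diameter [wave()] from [wall_diameter()].
#' @param pts,pbs Trimmed PTS/PBS trajectory tibbles (see
#'   [trim_plaque_edges()]).
#' @param spacing Pixels per mm.
#' @param cutoff,order High-pass settings, see [highpass()].
#' @param band Dominant-frequency search band, see [dominant_frequency()].
#' @return Tibble `cc_type, pair, sign, d_max` with one row per pixel pair
#'   and correlation type.
#' @export
plaque_measurements <- function(wall, pts, pbs, spacing = 12,
                                cutoff = 0.6, order = 4, band = c(0.6, 3)) {
  stopifnot(inherits(wall, "plq_wave"))
  fs <- frame_rate(wall)
  wall_f <- highpass(wall, cutoff = cutoff, order = order)
  cw <- dominant_frequency(wall_f, band = band)
  wall_w <- window_wave(wall_f, cw)

  pairs <- vertical_pairs(pts, pbs)
  if (nrow(pairs) == 0) {
    stop_plq("PTS and PBS share no vertically aligned pixel pairs", "no_pairs")
  }
  rt <- radial_series(pts, spacing); rb <- radial_series(pbs, spacing)
  lt <- longitudinal_series(pts, spacing); lb <- longitudinal_series(pbs, spacing)

  measure <- function(x, y, type) {
    cc <- cross_correlate(prep_wave(x, cw, cutoff, order),
                          prep_wave(y, cw, cutoff, order), cc_type = type)
    peak_measurement(cc)
  }

  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ia <- match(pairs$pixel_a[i], rt$pixel); ib <- match(pairs$pixel_b[i], rb$pixel)
    pts_r <- wave(rt$values[[ia]], fs, kind = "PTS_radial")
    pbs_r <- wave(rb$values[[ib]], fs, kind = "PBS_radial")
    pts_l <- wave(lt$values[[ia]], fs, kind = "PTS_longitudinal")
    pbs_l <- wave(lb$values[[ib]], fs, kind = "PBS_longitudinal")
    dist <- wave(abs(rt$values[[ia]] - rb$values[[ib]]), fs,
                 kind = "plaque_radial_distance")
    res <- list()
    res$CC1 <- tryCatch(measure(dist, wall, "CC1"), plaquesync_error = function(e) NULL)
    res$CC2 <- tryCatch(measure(pts_r, pbs_r, "CC2"), plaquesync_error = function(e) NULL)
    res$CC3 <- tryCatch(measure(pts_l, pbs_l, "CC3"), plaquesync_error = function(e) NULL)
    kept <- purrr::imap(purrr::compact(res), function(pk, nm) {
      tibble(cc_type = nm, pair = pairs$column[i], sign = pk$sign, d_max = pk$d_max)
    })
    list_rbind(kept)
  }) |> list_rbind()

  for (type in c("CC1", "CC2", "CC3")) {
    if (!any(out$cc_type == type)) {
      stop_plq(sprintf("no valid pixel pair produced a %s cross-correlation", type),
               "no_valid_pairs")
    }
  }
  out
}

# Fold per-pair measurements into the 24-feature row.
summarise_measurements <- function(measurements) {
  feats <- measurements |>
    group_by(.data$cc_type) |>
    summarise(sp = synchronisation_percentage(.data$sign),
              stats = list(lag_statistics(.data$d_max)), .groups = "drop") |>
    tidyr::unnest("stats")
  wide <- feats |>
    tidyr::pivot_longer(-"cc_type", names_to = "stat") |>
    mutate(name = paste0(.data$stat, "_", .data$cc_type)) |>
    select("name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
  select(wide, dplyr::all_of(cc_feature_names()))
}

#' The 24-feature synchronisation signature of a plaque
#'
#' Assembles, from the per-pair peak measurements of the three
#' cross-correlation types, the synchronisation percentage and the seven
#' phase-shift statistics per type: 24 features in total
#' (`sp_CC1 ... kurtosis_CC3`).
#'
#' @inheritParams plaque_measurements
#' @return A one-row tibble with 24 numeric feature columns.
#' @export
plaque_features <- function(wall, pts, pbs, spacing = 12,
                            cutoff = 0.6, order = 4, band = c(0.6, 3)) {
  summarise_measurements(
    plaque_measurements(wall, pts, pbs, spacing = spacing,
                        cutoff = cutoff, order = order, band = band))
}
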