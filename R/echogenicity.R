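#' Blood and adventitia reference regions
#'
#' Frame-1 pixel sets used to anchor grayscale normalisation: a region
#' inside the blood (lumen) and one in the adventitia. The adventitia must
#' be brighter than the blood.
#'
#' @param blood,adventitia Tibbles (or data frames) with integer columns
#'   `row`, `col`.
#' @return A `reference_regions` object.
#' @export
reference_regions <- function(blood, adventitia) {
  chk <- function(x, nm) {
    if (nrow(x) == 0 || !all(c("row", "col") %in% names(x))) {
      stop_plq(sprintf("`%s` must be a non-empty tibble with row/col", nm),
               "invalid_regions")
    }
    as_tibble(x[c("row", "col")])
  }
  blood <- chk(blood, "blood"); adventitia <- chk(adventitia, "adventitia")
  if (nrow(dplyr::inner_join(blood, adventitia, by = c("row", "col"))) > 0) {
    stop_plq("blood and adventitia regions must be disjoint", "invalid_regions")
  }
  structure(list(blood = blood, adventitia = adventitia),
            class = "reference_regions")
}

region_median <- function(frame, region) {
  median(frame[cbind(region$row, region$col)])
}

#' Normalise grayscale against blood and adventitia medians
#'
#' Linearly adjusts image intensities so the blood-region median maps to 0
#' and the adventitia-region median to 190 (the standard normalisation
#' target for plaque echogenicity analysis), clipping to `[0, 255]`.
#'
#' @param frame Numeric matrix of raw gray levels.
#' @param refs A [reference_regions()].
#' @return The normalised frame.
#' @examples
#' f <- matrix(c(10, 10, 200, 200, 105, 50), 2)
#' refs <- reference_regions(blood = data.frame(row = 1:2, col = 1),
#'                           adventitia = data.frame(row = 1:2, col = 2))
#' normalise_grayscale(f, refs)
#' @export
normalise_grayscale <- function(frame, refs) {
  stopifnot(inherits(refs, "reference_regions"))
  gb <- region_median(frame, refs$blood)
  ga <- region_median(frame, refs$adventitia)
  if (ga <= gb) {
    stop_plq("adventitia median must exceed blood median", "invalid_references")
  }
  clamp(190 * (frame - gb) / (ga - gb), 0, 255)
}

#' Plaque grayscale median (GSM) and echogenicity label
#'
#' Locates the plaque automatically in every frame from the tracked PTS and
#' PBS trajectories (the region between the two interfaces, column by
#' column, with half-open pixel-centre inclusion), computes the grayscale
#' median of the normalised intensities per frame, and averages the
#' per-frame GSMs. Plaques with GSM below 25 are labelled echolucent,
#' otherwise echogenic.
#'
#' @param seq An [image_sequence()] of raw frames.
#' @param pts,pbs Tracked PTS/PBS trajectory tibbles covering all frames.
#' @param refs A [reference_regions()] in frame-1 coordinates.
#' @param min_pixels Minimum plaque region size per frame.
#' @return A `plq_gsm` object: `per_frame` tibble (`frame, gsm, n_pixels`),
#'   `gsm` (mean over frames), `label`.
#' @export
plaque_gsm <- function(seq, pts, pbs, refs, min_pixels = 10) {
  stopifnot(inherits(seq, "image_sequence"))
  nt <- n_frames(seq)
  if (!setequal(unique(pts$frame), seq_len(nt)) ||
      !setequal(unique(pbs$frame), seq_len(nt))) {
    stop_plq("trajectories must cover every frame of the sequence", "invalid_trajectory")
  }
  dims <- frame_dim(seq)
  per_frame <- purrr::map(seq_len(nt), function(f) {
    top <- filter(pts, .data$frame == f)
    bot <- filter(pbs, .data$frame == f)
    c_lo <- max(1, ceiling(max(min(top$col), min(bot$col))))
    c_hi <- min(dims[2], floor(min(max(top$col), max(bot$col))))
    if (c_lo > c_hi) {
      stop_plq(sprintf("degenerate plaque region in frame %d", f), "degenerate_region")
    }
    cols <- seq.int(c_lo, c_hi)
    top_r <- approx(top$col, top$row, xout = cols, rule = 2)$y
    bot_r <- approx(bot$col, bot$row, xout = cols, rule = 2)$y
    norm <- normalise_grayscale(seq$frames[, , f], refs)
    vals <- unlist(purrr::map(seq_along(cols), function(i) {
      r_lo <- ceiling(top_r[i]); r_hi <- ceiling(bot_r[i]) - 1
      if (r_lo > r_hi) return(numeric(0))
      rr <- seq.int(max(1, r_lo), min(dims[1], r_hi))
      norm[rr, cols[i]]
    }))
    if (length(vals) < min_pixels) {
      stop_plq(sprintf("degenerate plaque region in frame %d (%d px)", f, length(vals)),
               "degenerate_region")
    }
    tibble(frame = f, gsm = median(vals), n_pixels = length(vals))
  }) |> list_rbind()
  gsm <- mean(per_frame$gsm)
  structure(list(per_frame = per_frame, gsm = gsm,
                 label = if (gsm < 25) "echolucent" else "echogenic"),
            class = "plq_gsm")
}

#' @export
print.plq_gsm <- function(x, ...) {
  cat(sprintf("<plq_gsm: GSM = %.1f over %d frames -> %s>\n",
              x$gsm, nrow(x$per_frame), x$label))
  invisible(x)
}

#' @export
tidy.plq_gsm <- function(x, ...) x$per_frame

#' @export
glance.plq_gsm <- function(x, ...) {
  tibble(gsm = x$gsm, label = x$label, n_frames = nrow(x$per_frame))
}
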