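#' Block-matching tracker configuration
#'
#' Settings for the adaptive block-matching tracker with Kalman smoothing.
#' Reference blocks are taken in the first frame, centred at each contour
#' pixel; each subsequent frame is searched around the Kalman-predicted
#' position ("adaptive" re-centring) while the reference texture is kept from
#' frame 1 to avoid drift accumulation. Similarity is normalised
#' cross-correlation with optional parabolic sub-pixel refinement; a
#' per-pixel constant-velocity Kalman filter smooths the measurements.
#'
#' @param block_mm Block size in mm as `c(radial, longitudinal)`; the default
#'   `c(1, 1.6)` gives the 1.6 x 1 mm^2 reference block (wide along the
#'   vessel axis).
#' @param search_radius Search radius in pixels around the predicted
#'   position; must be at least the maximum expected per-frame displacement.
#' @param subpixel Logical: refine the integer peak by a 1-D parabolic fit
#'   along each axis.
#' @param process_noise Kalman process (acceleration) noise variance, px^2.
#' @param measurement_noise Kalman measurement noise variance, px^2. Set to 0
#'   to trust block-matching measurements fully (no smoothing).
#' @return A `tracker_config` object.
#' @export
tracker_config <- function(block_mm = c(1, 1.6), search_radius = 5,
                           subpixel = TRUE, process_noise = 0.01,
                           measurement_noise = 0.25) {
  if (length(block_mm) != 2L || any(block_mm <= 0)) {
    stop_plq("`block_mm` must be two positive extents (radial, longitudinal)",
             "invalid_config")
  }
  if (!is_scalar_number(search_radius) || search_radius < 1) {
    stop_plq("`search_radius` must be >= 1 pixel", "invalid_config")
  }
  if (process_noise < 0 || measurement_noise < 0) {
    stop_plq("Kalman noise variances must be non-negative", "invalid_config")
  }
  structure(list(block_mm = block_mm, search_radius = as.integer(search_radius),
                 subpixel = isTRUE(subpixel), process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "tracker_config")
}

# Odd block half-sizes in pixels for a given spacing.
block_half_sizes <- function(cfg, spacing) {
  hb <- pmax(1L, floor(cfg$block_mm * spacing / 2))
  c(row = hb[1], col = hb[2])
}

# Precompute, for every offset (dy, dx) in the search square, the linear
# indices of the shifted block inside the search region matrix.
offset_index_table <- function(hb, radius) {
  br <- 2 * hb["row"] + 1; bc <- 2 * hb["col"] + 1
  sr <- br + 2 * radius
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  block_rows <- seq_len(br); block_cols <- seq_len(bc)
  cell <- as.integer(outer(block_rows, (block_cols - 1) * sr, "+"))
  idx <- vapply(seq_len(nrow(offs)), function(i) {
    as.integer(cell + (offs$dy[i] + radius) + (offs$dx[i] + radius) * sr)
  }, integer(length(cell)))
  list(offsets = offs, idx = idx, block_len = length(cell))
}

# NCC of the reference block against every candidate offset patch.
# ref0: centred reference values; S: search region matrix (vectorised).
ncc_scores <- function(svec, tab, ref0, ref_norm) {
  patches <- matrix(svec[tab$idx], nrow = tab$block_len)
  pm <- colMeans(patches)
  num <- as.vector(crossprod(patches, ref0))
  pvar <- colSums(patches^2) - tab$block_len * pm^2
  pvar[pvar < 1e-12] <- NA
  scores <- num / (sqrt(pvar) * ref_norm)
  scores[is.na(scores)] <- -Inf
  scores
}

# Offset choice with ties broken toward the smallest displacement magnitude,
# then lexicographically by (dy, dx).
pick_offset <- function(scores, offs) {
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1L) {
    mag <- offs$dy[cand]^2 + offs$dx[cand]^2
    cand <- cand[order(mag, offs$dy[cand], offs$dx[cand])]
  }
  cand[1]
}

# Parabolic 1-D refinement of the similarity peak along one axis.
parabolic_delta <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (cm - cp) / den
  clamp(d, -0.5, 0.5)
}

kalman_axis_step <- function(state, z, q, r) {
  # constant-velocity model, dt = 1 frame
  x <- c(state$x[1] + state$x[2], state$x[2])
  Fm <- matrix(c(1, 0, 1, 1), 2)
  Q <- q * matrix(c(0.25, 0.5, 0.5, 1), 2)
  P <- Fm %*% state$P %*% t(Fm) + Q
  S <- P[1, 1] + r
  K <- P[, 1] / S
  x <- x + K * (z - x[1])
  P <- (diag(2) - K %*% t(c(1, 0))) %*% P
  list(x = x, P = P)
}

#' Track ROI contours through an image sequence
#'
#' Estimates sub-pixel radial (row) and longitudinal (column) positions of
#' every contour pixel across all frames by adaptive block matching with
#' Kalman smoothing. Deterministic for fixed inputs.
#'
#' @param seq An [image_sequence()].
#' @param contours Tibble with columns `roi`, `pixel`, `row`, `col` (frame-1
#'   positions, 1-based).
#' @param cfg A [tracker_config()].
#' @return A tibble `roi, pixel, frame, row, col`; frame-1 positions equal
#'   the input contour.
#' @examples
#' ph <- generate_image_sequence(motion_model(duration = 3, seed = 7),
#'                               phantom_geometry())
#' head(track_rois(ph$seq, dplyr::filter(ph$contours, roi == "PTS",
#'                                       pixel %in% 1:3)))
#' @export
track_rois <- function(seq, contours, cfg = tracker_config()) {
  stopifnot(inherits(seq, "image_sequence"))
  if (!all(c("roi", "pixel", "row", "col") %in% names(contours))) {
    stop_plq("`contours` needs columns roi, pixel, row, col", "invalid_contour")
  }
  dims <- frame_dim(seq)
  nt <- n_frames(seq)
  hb <- block_half_sizes(cfg, seq$spacing)
  R <- cfg$search_radius
  tab <- offset_index_table(hb, R)
  margin_r <- hb["row"] + R
  margin_c <- hb["col"] + R
  if (2 * margin_r + 1 > dims[1] || 2 * margin_c + 1 > dims[2]) {
    stop_plq("block plus search window larger than the frame", "tracking_error")
  }
  frame1 <- seq$frames[, , 1]

  out <- vector("list", nrow(contours))
  for (i in seq_len(nrow(contours))) {
    r0 <- contours$row[i]; c0 <- contours$col[i]
    ri <- round(r0); ci <- round(c0)
    if (ri - hb["row"] < 1 || ri + hb["row"] > dims[1] ||
        ci - hb["col"] < 1 || ci + hb["col"] > dims[2]) {
      stop_plq(sprintf("reference block for %s pixel %s exits the image",
                       contours$roi[i], contours$pixel[i]), "tracking_error")
    }
    ref <- frame1[(ri - hb["row"]):(ri + hb["row"]), (ci - hb["col"]):(ci + hb["col"])]
    ref0 <- as.vector(ref) - mean(ref)
    ref_norm <- sqrt(sum(ref0^2))
    if (ref_norm < 1e-12) ref_norm <- 1  # flat reference: scores all 0, ties -> 0

    st_r <- list(x = c(r0, 0), P = diag(c(1, 1)))
    st_c <- list(x = c(c0, 0), P = diag(c(1, 1)))
    rows_out <- numeric(nt); cols_out <- numeric(nt)
    rows_out[1] <- r0; cols_out[1] <- c0

    for (f in 2:nt) {
      # search centred at the Kalman-predicted position; the predicted
      # per-frame step is capped at the search radius (a larger step could
      # not have been measured anyway)
      pr <- st_r$x[1] + clamp(st_r$x[2], -R, R)
      pc <- st_c$x[1] + clamp(st_c$x[2], -R, R)
      ctr_r <- clamp(round(pr), 1 + margin_r, dims[1] - margin_r)
      ctr_c <- clamp(round(pc), 1 + margin_c, dims[2] - margin_c)
      # recentring may absorb a transiently wild prediction, but a target
      # whose last position cannot be reached by the search is lost
      if (abs(ctr_r - st_r$x[1]) > 2 * R || abs(ctr_c - st_c$x[1]) > 2 * R) {
        stop_plq(sprintf("search window for %s pixel %s exits the image at frame %d",
                         contours$roi[i], contours$pixel[i], f), "tracking_error")
      }
      S <- seq$frames[(ctr_r - margin_r):(ctr_r + margin_r),
                      (ctr_c - margin_c):(ctr_c + margin_c), f]
      scores <- ncc_scores(as.vector(S), tab, ref0, ref_norm)
      k <- pick_offset(scores, tab$offsets)
      dy <- tab$offsets$dy[k]; dx <- tab$offsets$dx[k]
      sub_r <- 0; sub_c <- 0
      # a perfect correlation peak is an exact match: no refinement needed
      if (cfg$subpixel && scores[k] < 1 - 1e-12) {
        n_side <- 2 * R + 1
        iy <- dy + R + 1; ix <- dx + R + 1
        if (iy > 1 && iy < n_side) {
          sub_r <- parabolic_delta(scores[k - 1], scores[k], scores[k + 1])
        }
        if (ix > 1 && ix < n_side) {
          sub_c <- parabolic_delta(scores[k - n_side], scores[k], scores[k + n_side])
        }
      }
      zr <- ctr_r + dy + sub_r
      zc <- ctr_c + dx + sub_c
      st_r <- kalman_axis_step(st_r, zr, cfg$process_noise, cfg$measurement_noise)
      st_c <- kalman_axis_step(st_c, zc, cfg$process_noise, cfg$measurement_noise)
      rows_out[f] <- st_r$x[1]
      cols_out[f] <- st_c$x[1]
    }
    out[[i]] <- tibble(roi = contours$roi[i], pixel = contours$pixel[i],
                       frame = seq_len(nt), row = rows_out, col = cols_out)
  }
  list_rbind(out)
}

#' Displace a contour by a (possibly sub-pixel) offset
#'
#' Uniform translation of all contour pixels, used by the observer
#' variability experiment, which probes contour placements 0-2 pixels away
#' from the expert annotation.
#'
#' @param contour Tibble with columns `row`, `col` (and any others, kept).
#' @param offset Either a single number (applied to rows, i.e. radially) or
#'   `c(row_offset, col_offset)` in pixels. A warning is raised when the
#'   Euclidean magnitude falls outside `[0, 2]`, the range used by the
#'   variability experiment.
#' @return The translated contour tibble.
#' @export
displace_contour <- function(contour, offset) {
  if (length(offset) == 1L) offset <- c(offset, 0)
  if (length(offset) != 2L || !is.numeric(offset)) {
    stop_plq("`offset` must be one or two numbers (pixels)", "invalid_contour")
  }
  mag <- sqrt(sum(offset^2))
  if (mag > 2) {
    warn("contour offset magnitude outside [0, 2] px; beyond the variability-study range")
  }
  mutate(contour, row = .data$row + offset[1], col = .data$col + offset[2])
}
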