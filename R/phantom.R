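#' Geometry of the synthetic carotid phantom
#'
#' Describes a longitudinal-section B-mode phantom: an anterior wall-lumen
#' interface (AWL), a dark lumen, a plaque sitting on the posterior wall
#' between its top (PTS) and bottom (PBS) surfaces, the posterior wall-lumen
#' interface (PWL) on the adjacent non-atheromatous wall, and bright
#' adventitia below. Depths are in mm from the top of the image.
#'
#' @param n_rows,n_cols Image size in pixels.
#' @param spacing Pixels per mm (default 12).
#' @param awl_depth,pts_depth,pbs_depth,pwl_depth Interface depths in mm;
#'   must satisfy `awl < pts < pbs <= pwl` (plaque inside the lumen band,
#'   PTS strictly above PBS).
#' @param plaque_cols Integer range (length 2) of columns spanned by the
#'   plaque; defaults to the central 60 percent of the image width.
#' @param lumen_intensity,plaque_intensity,adventitia_intensity,tissue_intensity
#'   Mean gray levels (0-255) of blood, plaque, adventitia and other tissue;
#'   adventitia must be brighter than the lumen.
#' @param speckle_sd Relative standard deviation of the multiplicative
#'   speckle texture.
#' @param speckle_corr Speckle correlation length in pixels (Gaussian
#'   smoothing sigma of the texture).
#' @param intensity_noise_sd Standard deviation (gray levels) of additive
#'   per-frame electronic noise.
#' @return A `phantom_geometry` object.
#' @export
phantom_geometry <- function(n_rows = 96, n_cols = 160, spacing = 12,
                             awl_depth = 2, pts_depth = 3.4, pbs_depth = 4.8,
                             pwl_depth = 5.6, plaque_cols = NULL,
                             plateau_halfwidth = 0.3,
                             lumen_intensity = 15, plaque_intensity = 90,
                             adventitia_intensity = 200, tissue_intensity = 120,
                             speckle_sd = 0.3, speckle_corr = 1.5,
                             intensity_noise_sd = 2) {
  if (is.null(plaque_cols)) {
    half <- floor(0.3 * n_cols)
    plaque_cols <- c(floor(n_cols / 2) - half, floor(n_cols / 2) + half)
  }
  g <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            spacing = spacing, awl_depth = awl_depth, pts_depth = pts_depth,
            pbs_depth = pbs_depth, pwl_depth = pwl_depth,
            plaque_cols = as.integer(plaque_cols),
            plateau_halfwidth = plateau_halfwidth,
            lumen_intensity = lumen_intensity, plaque_intensity = plaque_intensity,
            adventitia_intensity = adventitia_intensity,
            tissue_intensity = tissue_intensity,
            speckle_sd = speckle_sd, speckle_corr = speckle_corr,
            intensity_noise_sd = intensity_noise_sd)
  if (!(g$awl_depth < g$pts_depth && g$pts_depth < g$pbs_depth &&
        g$pbs_depth <= g$pwl_depth)) {
    stop_plq("interface depths must satisfy awl < pts < pbs <= pwl", "invalid_geometry")
  }
  # each interface carries a coherent tissue layer of +/- plateau_halfwidth;
  # the layers must not overlap or the displacement field is ill-defined
  gaps <- diff(c(g$awl_depth, g$pts_depth, g$pbs_depth, g$pwl_depth))
  if (g$plateau_halfwidth < 0 || any(gaps <= 2 * g$plateau_halfwidth)) {
    stop_plq("interface plateaus overlap: reduce `plateau_halfwidth` or space the interfaces",
             "invalid_geometry")
  }
  if (g$adventitia_intensity <= g$lumen_intensity) {
    stop_plq("adventitia must be brighter than the lumen", "invalid_geometry")
  }
  if (g$pwl_depth * g$spacing >= g$n_rows || g$plaque_cols[1] < 1 ||
      g$plaque_cols[2] > g$n_cols || g$plaque_cols[1] >= g$plaque_cols[2]) {
    stop_plq("geometry does not fit inside the image", "invalid_geometry")
  }
  structure(g, class = "phantom_geometry")
}

# Gaussian smoothing of a matrix by separable convolution with edge
# replication; sigma in pixels.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], hw), v, rep(v[length(v)], hw))
    as.numeric(stats::filter(vp, k, sides = 2))[(hw + 1):(hw + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

# Piecewise-constant tissue intensity map of the phantom at rest.
phantom_intensity_map <- function(geom) {
  px <- function(d) d * geom$spacing
  rows <- seq_len(geom$n_rows)
  base_col <- ifelse(rows < px(geom$awl_depth), geom$tissue_intensity,
              ifelse(rows < px(geom$pwl_depth), geom$lumen_intensity,
                     geom$adventitia_intensity))
  img <- matrix(base_col, geom$n_rows, geom$n_cols)
  pc <- geom$plaque_cols
  in_plaque_rows <- rows >= px(geom$pts_depth) & rows < px(geom$pbs_depth)
  wall_rows <- rows >= px(geom$pbs_depth) & rows < px(geom$pwl_depth)
  img[in_plaque_rows, pc[1]:pc[2]] <- geom$plaque_intensity
  img[wall_rows, pc[1]:pc[2]] <- geom$tissue_intensity
  img
}

# Bilinear sampling of matrix `m` at (possibly fractional) coordinates,
# clamped to the image border.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- clamp(rows, 1, nr); cols <- clamp(cols, 1, nc)
  r1 <- clamp(floor(rows), 1, nr - 1); c1 <- clamp(floor(cols), 1, nc - 1)
  wr <- rows - r1; wc <- cols - c1
  i11 <- cbind(r1, c1); i21 <- cbind(r1 + 1, c1)
  i12 <- cbind(r1, c1 + 1); i22 <- cbind(r1 + 1, c1 + 1)
  m[i11] * (1 - wr) * (1 - wc) + m[i21] * wr * (1 - wc) +
    m[i12] * (1 - wr) * wc + m[i22] * wr * wc
}

#' Generate a speckle-textured phantom image sequence with known motion
#'
#' Builds a speckled tissue map from the geometry, then warps it frame by
#' frame with an analytic displacement field: the anterior and posterior
#' walls move apart and back with the cardiac pulse (diameter pulsation),
#' the plaque bottom surface follows the posterior wall delayed by
#' `wall_plaque_delay`, and the plaque top surface is further delayed by
#' `top_bottom_delay`. Displacements are interpolated over depth between
#' those interface anchors (pinned to zero at the top and bottom image
#' edges) and the warp inverts the forward map exactly, so the returned
#' ground-truth trajectories are exact.
#'
#' @param model A [motion_model()].
#' @param geom A [phantom_geometry()].
#' @return A list with `seq` (an [image_sequence()]), `truth` (tibble
#'   `roi, pixel, frame, row, col` of exact sub-pixel positions), and
#'   `contours` (tibble `roi, pixel, row, col` of first-frame contours).
#' @examples
#' ph <- generate_image_sequence(motion_model(duration = 3, seed = 1),
#'                               phantom_geometry())
#' ph$seq
#' @export
generate_image_sequence <- function(model, geom) {
  validate_motion_model(model)
  if (!inherits(geom, "phantom_geometry")) {
    stop_plq("`geom` must be a phantom_geometry()", "invalid_geometry")
  }
  with_rng(model$seed, {
    t <- model_times(model)
    nt <- length(t)
    fs <- model$frame_rate
    px <- function(d) d * geom$spacing
    pulse <- function(tt) cardiac_pulse(tt, model$fundamental_freq, model$n_harmonics)

    # Interface anchor displacements, mm -> px, per frame. Radial motion:
    # walls move apart by the pulse; plaque surfaces follow the posterior
    # wall with their delays. Longitudinal motion: whole wall band
    # translates, plaque surfaces delayed as above.
    a_r <- model$radial_amp * geom$spacing
    a_l <- model$longitudinal_amp * geom$spacing
    drift <- nuisance_terms(model, t) * geom$spacing  # common transducer drift, px
    jit <- function() if (model$noise_sd > 0) rnorm(nt, 0, model$noise_sd * geom$spacing) else 0
    disp_r <- list(
      AWL = -a_r * pulse(t) + drift + jit(),
      PTS = a_r * pulse(t - model$wall_plaque_delay - model$top_bottom_delay) + drift + jit(),
      PBS = a_r * pulse(t - model$wall_plaque_delay) + drift + jit(),
      PWL = a_r * pulse(t) + drift + jit())
    disp_l <- list(
      AWL = a_l * pulse(t),
      PTS = a_l * pulse(t - model$wall_plaque_delay - model$top_bottom_delay),
      PBS = a_l * pulse(t - model$wall_plaque_delay),
      PWL = a_l * pulse(t))

    anchor_row <- c(AWL = px(geom$awl_depth), PTS = px(geom$pts_depth),
                    PBS = px(geom$pbs_depth), PWL = px(geom$pwl_depth))

    # Bounds check: anchors must stay inside the frame at all times.
    for (nm in names(anchor_row)) {
      pos <- anchor_row[[nm]] + disp_r[[nm]]
      if (any(pos < 1 | pos > geom$n_rows)) {
        stop_plq(sprintf("displacement drives %s outside the image", nm),
                 "generation_error")
      }
    }

    base <- phantom_intensity_map(geom)
    speck <- matrix(rnorm(geom$n_rows * geom$n_cols), geom$n_rows)
    speck <- smooth_matrix(speck, geom$speckle_corr)
    speck <- speck / stats::sd(speck)
    texture <- clamp(base * (1 + geom$speckle_sd * speck), 0, 255)

    rows <- seq_len(geom$n_rows)
    cols <- seq_len(geom$n_cols)
    pc <- geom$plaque_cols
    in_plaque_col <- cols >= pc[1] & cols <= pc[2]

    # Depth profile of displacement for one column group at one frame.
    # Each interface carries a coherent layer (constant displacement over
    # +/- plateau_halfwidth around it, as a tissue layer moving rigidly);
    # between layers, and toward the pinned image edges, the field is
    # linearly interpolated.
    hw_px <- geom$plateau_halfwidth * geom$spacing
    depth_profile <- function(anchors_r, anchors_v) {
      ord <- order(anchors_r)
      ar <- anchors_r[ord]; av <- anchors_v[ord]
      xs <- c(1, as.vector(rbind(ar - hw_px, ar + hw_px)), geom$n_rows)
      ys <- c(0, rep(av, each = 2), 0)
      keep <- !duplicated(xs)
      approx(x = xs[keep], y = ys[keep], xout = rows, rule = 2)$y
    }

    frames <- array(0, dim = c(geom$n_rows, geom$n_cols, nt))
    groups <- list(
      plaque = list(cols = in_plaque_col, anchors = c("AWL", "PTS", "PBS", "PWL")),
      wall = list(cols = !in_plaque_col, anchors = c("AWL", "PWL")))

    for (f in seq_len(nt)) {
      frm <- matrix(0, geom$n_rows, geom$n_cols)
      for (grp in groups) {
        if (!any(grp$cols)) next
        ur <- depth_profile(anchor_row[grp$anchors],
                            vapply(grp$anchors, function(a) disp_r[[a]][f], 0))
        ul <- depth_profile(anchor_row[grp$anchors],
                            vapply(grp$anchors, function(a) disp_l[[a]][f], 0))
        fwd <- rows + ur
        if (any(diff(fwd) <= 0)) {
          stop_plq("radial displacement field folds over itself", "generation_error")
        }
        # exact inverse of the forward row map, then the row-wise
        # longitudinal shift evaluated at the source row
        src_row <- approx(x = fwd, y = rows, xout = rows, rule = 2)$y
        src_shift <- approx(x = rows, y = ul, xout = src_row, rule = 2)$y
        gcols <- which(grp$cols)
        rc <- matrix(src_row, geom$n_rows, length(gcols))
        cc <- outer(rep(1, geom$n_rows), gcols) - matrix(src_shift, geom$n_rows, length(gcols))
        frm[, gcols] <- bilinear_sample(texture, as.vector(rc), as.vector(cc))
      }
      if (geom$intensity_noise_sd > 0) {
        frm <- frm + rnorm(length(frm), 0, geom$intensity_noise_sd)
      }
      frames[, , f] <- clamp(frm, 0, 255)
    }

    ctr_cols <- pc[1]:pc[2]
    # contours are the frame-1 positions (the pulse is not zero at t = 0)
    contours <- purrr::map(c("AWL", "PTS", "PBS", "PWL"), function(nm) {
      tibble(roi = nm, pixel = seq_along(ctr_cols),
             row = anchor_row[[nm]] + disp_r[[nm]][1],
             col = ctr_cols + disp_l[[nm]][1])
    }) |> list_rbind()
    truth <- purrr::map(c("AWL", "PTS", "PBS", "PWL"), function(nm) {
      tidyr::expand_grid(pixel = seq_along(ctr_cols), frame = seq_len(nt)) |>
        mutate(roi = nm,
               row = anchor_row[[nm]] + disp_r[[nm]][.data$frame],
               col = ctr_cols[.data$pixel] + disp_l[[nm]][.data$frame]) |>
        select("roi", "pixel", "frame", "row", "col")
    }) |> list_rbind()
    if (any(truth$col < 1 | truth$col > geom$n_cols)) {
      stop_plq("longitudinal displacement drives a contour outside the image",
               "generation_error")
    }

    list(seq = image_sequence(frames, frame_rate = fs, spacing = geom$spacing),
         truth = truth, contours = contours)
  })
}
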