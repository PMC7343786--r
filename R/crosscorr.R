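#' Normalised cross-correlation over all lags
#'
#' Computes, for two equal-length series \eqn{x(i)} and \eqn{y(i)}
#' (\eqn{i = 1..N}), the mean-subtracted cross-correlation
#' \deqn{r_d = \frac{\sum_i (x(i)-m_x)(y(i-d)-m_y)}
#'                  {\sqrt{\sum_i (x(i)-m_x)^2}\sqrt{\sum_i (y(i)-m_y)^2}}}
#' for every lag \eqn{d = -(N-1), \ldots, N-1}, so the resulting sequence is
#' twice as long (minus one) as the inputs. The denominator normalises the
#' coefficients so that the cross-correlation of a series with itself is
#' exactly 1 at lag 0; mean subtraction makes signals from different
#' subjects comparable.
#'
#' @param x,y [wave()] objects (or numeric vectors sharing `frame_rate` via
#'   `x`), equal length, non-constant.
#' @param cc_type Label for the correlation type (`"CC1"`, `"CC2"`, `"CC3"`
#'   or free text).
#' @return A `plq_cc` object: list with `r` (length `2N - 1`), `lag`
#'   (samples), `frame_rate`, `cc_type`.
#' @examples
#' w <- wave(sin(2 * pi * seq(0, 2, by = 0.04)), 25)
#' cc <- cross_correlate(w, w)
#' cc$r[cc$lag == 0]  # exactly 1
#' @export
cross_correlate <- function(x, y, cc_type = "CC") {
  fs <- if (inherits(x, "plq_wave")) frame_rate(x) else NA_real_
  if (inherits(x, "plq_wave") && inherits(y, "plq_wave") &&
      !isTRUE(all.equal(frame_rate(x), frame_rate(y)))) {
    stop_plq("series must share one sampling rate", "invalid_correlation")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) {
    stop_plq("series must have equal lengths", "invalid_correlation")
  }
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom < 1e-12) {
    stop_plq("constant input: cross-correlation undefined (zero denominator)",
             "undefined_correlation")
  }
  # direct evaluation over the valid overlap of each lag (exact, and the
  # self-correlation at lag 0 is exactly 1)
  r <- vapply(-(n - 1):(n - 1), function(d) {
    i <- seq.int(max(1, 1 + d), min(n, n + d))
    sum(xc[i] * yc[i - d])
  }, 0) / denom
  structure(list(r = as.numeric(r), lag = -(n - 1):(n - 1),
                 frame_rate = fs, cc_type = cc_type),
            class = "plq_cc")
}

#' @export
print.plq_cc <- function(x, ...) {
  cat(sprintf("<plq_cc %s: %d lags, peak |r| = %.3f>\n",
              x$cc_type, length(x$r), max(abs(x$r))))
  invisible(x)
}

#' @export
as_tibble.plq_cc <- function(x, ...) {
  tibble(lag = x$lag, lag_s = if (is.na(x$frame_rate)) NA_real_ else x$lag / x$frame_rate,
         r = x$r, cc_type = x$cc_type)
}

#' @export
autoplot.plq_cc <- function(object, ...) {
  df <- as_tibble(object)
  pk <- peak_measurement(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$r)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(data = df[which.max(abs(df$r)), ], colour = "firebrick") +
    ggplot2::labs(x = "lag (s)", y = expression(r[d]),
                  title = sprintf("%s: sign %+d, phase shift %.2f s",
                                  object$cc_type, pk$sign, pk$d_max)) +
    ggplot2::theme_minimal()
}

#' Peak sign and phase shift of a cross-correlation
#'
#' Locates the maximum-absolute-correlation peak and returns its sign (+1:
#' in-phase motion, -1: out-of-phase) and the corresponding absolute lag
#' `d_max` in seconds. Ties in \eqn{|r|} are broken toward the smallest
#' absolute lag (favouring synchrony), then lexicographically.
#'
#' @param cc A `plq_cc` from [cross_correlate()].
#' @return One-row tibble: `sign`, `d_max` (s), `lag` (samples), `r_peak`.
#' @export
peak_measurement <- function(cc) {
  stopifnot(inherits(cc, "plq_cc"))
  a <- abs(cc$r)
  if (max(a) < 1e-12) {
    stop_plq("all-zero cross-correlation series", "undefined_peak")
  }
  cand <- which(a >= max(a) - 1e-12)
  if (length(cand) > 1L) {
    cand <- cand[order(abs(cc$lag[cand]), cc$lag[cand])]
  }
  k <- cand[1]
  tibble(sign = as.integer(sign(cc$r[k])),
         d_max = abs(cc$lag[k]) / cc$frame_rate,
         lag = cc$lag[k],
         r_peak = cc$r[k])
}

#' Phase shift between two displacement waveforms
#'
#' One-pair convenience pipeline: both series are high-pass filtered
#' (zero-phase), confined to the average cycle window estimated from the
#' first series, cross-correlated, and the peak sign and phase shift
#' extracted.
#'
#' @param x,y [wave()] objects of equal length and sampling rate.
#' @param cutoff,order High-pass settings, see [highpass()].
#' @param band Dominant-frequency search band, see [dominant_frequency()].
#' @return One-row tibble: `sign`, `d_max` (s), `lag`, `r_peak`, `f0` (Hz).
#' @examples
#' m <- motion_model(top_bottom_delay = 0.2, fundamental_freq = 1, seed = 8)
#' pair <- generate_waveform_pair(m)
#' estimate_delay(pair$x, pair$y)
#' @export
estimate_delay <- function(x, y, cutoff = 0.6, order = 4, band = c(0.6, 3)) {
  xf <- highpass(x, cutoff = cutoff, order = order)
  yf <- highpass(y, cutoff = cutoff, order = order)
  cw <- dominant_frequency(xf, band = band)
  pk <- peak_measurement(cross_correlate(window_wave(xf, cw), window_wave(yf, cw)))
  mutate(pk, f0 = cw$f0)
}

#' Synchronisation percentage
#'
#' Percentage of positive values in a set of maximum signed
#' cross-correlation values (one per PTS-PBS pair): the proportion of plaque
#' pairs exhibiting synchronous (in-phase) motion.
#'
#' @param signs Vector of +1/-1 peak signs.
#' @return Percentage in `[0, 100]`.
#' @examples
#' synchronisation_percentage(c(1, 1, -1, 1, -1, 1, 1, 1, 1, 1))  # 80
#' @export
synchronisation_percentage <- function(signs) {
  if (length(signs) == 0) {
    stop_plq("empty sign set", "empty_input")
  }
  if (!all(signs %in% c(-1, 1))) {
    stop_plq("signs must be +1 or -1", "invalid_signs")
  }
  100 * sum(signs > 0) / length(signs)
}

#' Histogram statistics of phase shifts
#'
#' The seven statistics (maximum, minimum, mean, median, standard deviation,
#' skewness, excess kurtosis) of the `d_max` phase shifts over all pixel
#' pairs of a plaque. Standard deviation uses the n-1 divisor; skewness and
#' kurtosis are moment-based standardised central moments (kurtosis excess,
#' so a normal sample gives 0); a constant set yields 0 for all three by
#' convention.
#'
#' @param lags Vector of phase shifts in seconds.
#' @return One-row tibble with columns `max, min, mean, median, stdev,
#'   skewness, kurtosis`.
#' @export
lag_statistics <- function(lags) {
  if (length(lags) == 0) {
    stop_plq("empty lag set", "empty_input")
  }
  n <- length(lags)
  m <- mean(lags)
  m2 <- mean((lags - m)^2)
  if (n < 2 || m2 < 1e-24) {
    s <- 0; g1 <- 0; g2 <- 0
  } else {
    s <- stats::sd(lags)
    g1 <- mean((lags - m)^3) / m2^1.5
    g2 <- mean((lags - m)^4) / m2^2 - 3
  }
  tibble(max = max(lags), min = min(lags), mean = m, median = median(lags),
         stdev = s, skewness = g1, kurtosis = g2)
}
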