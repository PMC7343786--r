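# Independent brute-force oracles used across the suite. These deliberately
# use naive loops so they share no code path with the package internals.

# Direct double-loop evaluation of the mean-subtracted, norm-normalised
# cross-correlation for all lags -(N-1)..(N-1).
oracle_crosscorr <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  sapply(-(n - 1):(n - 1), function(d) {
    s <- 0
    for (i in seq_len(n)) {
      j <- i - d
      if (j >= 1 && j <= n) s <- s + xc[i] * yc[j]
    }
    s / den
  })
}

# Oracle peak: argmax |r|, ties to smallest |lag| then smallest lag.
oracle_peak <- function(r, lags) {
  a <- abs(r)
  cand <- which(a >= max(a) - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  list(lag = lags[cand[1]], sign = sign(r[cand[1]]))
}

# Exhaustive integer-shift normalised-correlation search: the ground truth
# for block-matching on integer translations.
oracle_integer_shift <- function(ref_frame, target_frame, centre, half_block,
                                 radius) {
  rr <- (centre[1] - half_block[1]):(centre[1] + half_block[1])
  cc <- (centre[2] - half_block[2]):(centre[2] + half_block[2])
  ref <- ref_frame[rr, cc]
  ref0 <- ref - mean(ref)
  best <- c(NA, NA); best_score <- -Inf
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      patch <- target_frame[rr + dy, cc + dx]
      p0 <- patch - mean(patch)
      den <- sqrt(sum(ref0^2) * sum(p0^2))
      score <- if (den < 1e-12) 0 else sum(ref0 * p0) / den
      if (score > best_score + 1e-12 ||
          (score > best_score - 1e-12 &&
           (dy^2 + dx^2) < sum(best^2))) {
        best <- c(dy, dx); best_score <- score
      }
    }
  }
  best
}

# Periodogram peak frequency by direct DFT sum (no fft()).
oracle_dominant_freq <- function(x, fs, band = c(0.6, 3)) {
  n <- length(x)
  x <- x - mean(x)
  freqs <- (seq_len(floor(n / 2))) * fs / n
  power <- sapply(seq_along(freqs), function(k) {
    w <- 2 * pi * k * (0:(n - 1)) / n
    (sum(x * cos(w))^2 + sum(x * sin(w))^2) / n
  })
  keep <- freqs >= band[1] & freqs <= band[2]
  freqs[keep][which.max(power[keep])]
}

# Moment statistics by direct formulas.
oracle_stats <- function(v) {
  n <- length(v); m <- mean(v)
  m2 <- sum((v - m)^2) / n
  list(max = max(v), min = min(v), mean = m, median = median(v),
       stdev = sqrt(sum((v - m)^2) / (n - 1)),
       skewness = (sum((v - m)^3) / n) / m2^1.5,
       kurtosis = (sum((v - m)^4) / n) / m2^2 - 3)
}

# A clean sinusoidal test wave.
sine_wave <- function(freq, fs = 25, duration = 5, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  wave(amp * sin(2 * pi * freq * t + phase), fs)
}

# Small speckle-texture frame for tracking tests.
speckle_frame <- function(n_rows, n_cols, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_rows * n_cols, 0, 255), n_rows, n_cols)
  # mild smoothing so correlation peaks are well-behaved
  (m + cbind(m[, -1], m[, ncol(m)]) + rbind(m[-1, ], m[nrow(m), ])) / 3
}

# Thin phantom contours to speed up tracking-heavy tests; original pixel
# ids are kept so results still join against the generator's ground truth.
thin_contours <- function(ctr, plaque_stride = 2, wall_stride = 3) {
  dplyr::filter(ctr,
                (roi %in% c("PTS", "PBS") & pixel %% plaque_stride == 1) |
                  (roi %in% c("AWL", "PWL") & pixel %% wall_stride == 1))
}
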