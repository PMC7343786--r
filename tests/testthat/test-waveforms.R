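# Trajectory builders: pixel k at column 2k, radial row r(t), all in px.
traj_from_rows <- function(row_fun, n_pixels = 8, n_frames = 100, roi = "PTS",
                           col_jitter = 0) {
  purrr::map(seq_len(n_pixels), function(p) {
    tibble::tibble(roi = roi, pixel = p, frame = seq_len(n_frames),
                   row = row_fun(p, (seq_len(n_frames) - 1) / 25),
                   col = 2 * p + col_jitter)
  }) |> purrr::list_rbind()
}

test_that("edge trimming removes exactly n_trim pixels per side", {
  traj <- traj_from_rows(function(p, t) 40 + 0 * t, n_pixels = 120)
  trimmed <- trim_plaque_edges(traj, 25)
  expect_identical(length(unique(trimmed$pixel)), 70L)
  expect_identical(sort(unique(trimmed$pixel)), 26:95)
  expect_identical(trim_plaque_edges(traj, 0), traj)
  short <- traj_from_rows(function(p, t) 40 + 0 * t, n_pixels = 50)
  expect_error(trim_plaque_edges(short, 25), class = "too_short_plaque")
})

test_that("wall diameter superposes anti-phase interfaces and picks clean columns", {
  fs <- 25; t <- (0:99) / 25; a <- 3  # px
  awl <- traj_from_rows(function(p, tt) 24 - a * sin(2 * pi * tt), roi = "AWL")
  pwl <- traj_from_rows(function(p, tt) 60 + a * sin(2 * pi * tt), roi = "PWL")
  w <- wall_diameter(awl, pwl, frame_rate = fs, spacing = 12)
  # amplitude doubles: diameter = (36 + 2a sin)/12 mm (up to sampling of
  # the sinusoid extremes at 25 fps)
  expect_equal(max(w) - min(w), 2 * 2 * a / 12, tolerance = 0.01)
  expect_identical(attr(w, "kind"), "wall_diameter")

  # a single noisy column among clean ones is not selected
  set.seed(2)
  pwl_noisy <- dplyr::mutate(pwl, row = ifelse(pixel == 3, row + rnorm(dplyr::n(), 0, 6), row))
  w2 <- wall_diameter(awl, pwl_noisy, frame_rate = fs, spacing = 12)
  expect_false(attr(w2, "column") == 6)  # column of pixel 3

  # static interfaces: degenerate, flagged
  awl0 <- traj_from_rows(function(p, tt) 24 + 0 * tt, roi = "AWL")
  pwl0 <- traj_from_rows(function(p, tt) 60 + 0 * tt, roi = "PWL")
  expect_error(wall_diameter(awl0, pwl0, frame_rate = fs, spacing = 12),
               class = "no_cyclic_motion")
})

test_that("plaque radial distance matches the closed form for delayed sinusoids", {
  fs <- 25; a <- 3; tau <- 0.2; f0 <- 1
  pts <- traj_from_rows(function(p, tt) 40 + a * sin(2 * pi * f0 * (tt - tau)))
  pbs <- traj_from_rows(function(p, tt) 58 + a * sin(2 * pi * f0 * tt), roi = "PBS")
  d <- plaque_radial_distance(pts, pbs, frame_rate = fs, spacing = 12)
  expect_length(d, 8)
  # |pts - pbs| = |18 + a(sin delayed - sin)|: difference of delayed sinusoids
  # is a sinusoid of amplitude 2 a sin(pi f0 tau) around the 18 px baseline
  amp <- 2 * a * sin(pi * f0 * tau) / 12
  one <- as.numeric(d[[1]])
  expect_equal((max(one) - min(one)) / 2, amp, tolerance = 0.01)
  # identical motion: constant distance
  d0 <- plaque_radial_distance(
    traj_from_rows(function(p, tt) 40 + a * sin(2 * pi * tt)),
    traj_from_rows(function(p, tt) 58 + a * sin(2 * pi * tt), roi = "PBS"),
    frame_rate = fs, spacing = 12)
  expect_equal(diff(range(as.numeric(d0[[1]]))), 0, tolerance = 1e-9)
  # symmetry under swapping top and bottom
  d_sw <- plaque_radial_distance(pbs, pts, frame_rate = fs, spacing = 12)
  expect_equal(as.numeric(d_sw[[1]]), as.numeric(d[[1]]), tolerance = 1e-12)
})

test_that("high-pass filter attenuates as a 4th-order Butterworth, zero phase", {
  fs <- 25
  # constant in, ~zero out
  const <- wave(rep(3.2, 100), fs)
  expect_lte(max(abs(highpass(const))), 1e-6)
  # 1.2 Hz passes almost unchanged (two-pass |H|^2 with |H| = (1+(fc/f)^8)^-1/2)
  s12 <- sine_wave(1.2, duration = 20)
  out <- highpass(s12)
  gain2 <- 1 / (1 + (0.6 / 1.2)^8)
  mid <- 150:350
  expect_equal(max(abs(as.numeric(out)[mid])), gain2, tolerance = 0.01)
  # 0.1 Hz drift is crushed by > 99.9 %
  s01 <- sine_wave(0.1, duration = 40)
  expect_lte(max(abs(as.numeric(highpass(s01))[300:700])), 0.001)
  # linearity
  x <- sine_wave(1.1, duration = 10); y <- sine_wave(1.7, duration = 10, phase = 1)
  lhs <- highpass(wave(2 * as.numeric(x) + 3 * as.numeric(y), fs))
  rhs <- 2 * as.numeric(highpass(x)) + 3 * as.numeric(highpass(y))
  expect_equal(as.numeric(lhs), rhs, tolerance = 1e-9)
  # too-short series
  expect_error(highpass(wave(rnorm(10), fs)), class = "too_short_series")
})

test_that("zero-phase filtering preserves the cross-correlation peak lag", {
  x <- sine_wave(1, duration = 8, phase = 0)
  y <- sine_wave(1, duration = 8, phase = -2 * pi * 1 * 0.2)  # 0.2 s delay
  raw_pk <- oracle_peak(oracle_crosscorr(as.numeric(x), as.numeric(y)),
                        -(length(x) - 1):(length(x) - 1))
  filt_pk <- peak_measurement(cross_correlate(highpass(x), highpass(y)))
  expect_identical(filt_pk$lag, as.integer(raw_pk$lag))
})

test_that("dominant frequency finds the in-band periodogram peak", {
  w <- sine_wave(1, duration = 10)
  cw <- dominant_frequency(w)
  expect_lte(abs(cw$f0 - 1), 25 / length(w))
  expect_identical(cw$window_length, as.integer(round(25 / cw$f0)))
  expect_lte(cw$start + cw$window_length - 1, length(w))
  # two harmonics: the stronger one wins
  t <- seq(0, 10 - 0.04, by = 0.04)
  mix <- wave(sin(2 * pi * t) + 0.3 * sin(4 * pi * t), 25)
  expect_lte(abs(dominant_frequency(mix)$f0 - 1), 25 / length(mix))
  expect_equal(dominant_frequency(mix)$f0,
               oracle_dominant_freq(as.numeric(mix), 25), tolerance = 1e-9)
  # white noise: no dominant frequency
  set.seed(5)
  expect_error(dominant_frequency(wave(rnorm(250), 25)),
               class = "no_dominant_frequency")
})

test_that("the cycle window starts after the filter warm-up when room allows", {
  w <- sine_wave(1, duration = 10)  # 250 samples
  cw <- dominant_frequency(w)
  expect_gte(cw$start, round(25 / 0.6))
  # short recording: latest start that still fits
  w2 <- sine_wave(1, duration = 3)
  cw2 <- dominant_frequency(w2)
  expect_lte(cw2$start + cw2$window_length - 1, length(w2))
})
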