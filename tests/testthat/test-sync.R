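test_that("cross-correlation is unit-normalised at lag zero", {
  w <- sine_wave(1.2, duration = 4)
  cc <- cross_correlate(w, w)
  expect_identical(cc$r[cc$lag == 0], 1)
  neg <- cross_correlate(w, wave(-as.numeric(w), 25))
  expect_equal(neg$r[neg$lag == 0], -1, tolerance = 1e-12)
  expect_identical(length(cc$r), 2L * length(w) - 1L)
  expect_true(all(abs(cc$r) <= 1 + 1e-12))
})

test_that("the full lag sequence agrees with the direct-sum oracle", {
  x <- c(1, 2, 3, 4); y <- c(4, 3, 2, 1)
  cc <- cross_correlate(wave(x, 25), wave(y, 25))
  expect_equal(cc$r, oracle_crosscorr(x, y), tolerance = 1e-12)

  set.seed(101)
  for (i in 1:20) {
    n <- sample(8:64, 1)
    x <- rnorm(n); y <- rnorm(n)
    cc <- cross_correlate(wave(x, 25), wave(y, 25))
    expect_equal(cc$r, oracle_crosscorr(x, y), tolerance = 1e-10)
  }
})

test_that("cross-correlation symmetry and affine invariance hold", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    rxy <- cross_correlate(wave(x, 25), wave(y, 25))
    ryx <- cross_correlate(wave(y, 25), wave(x, 25))
    expect_equal(rxy$r, rev(ryx$r), tolerance = 1e-10)
    raff <- cross_correlate(wave(2.5 * x + 7, 25), wave(y, 25))
    expect_equal(raff$r, rxy$r, tolerance = 1e-10)
  }
})

test_that("constant input raises an undefined-correlation error", {
  expect_error(cross_correlate(wave(rep(1, 10), 25), wave(rnorm(10), 25)),
               class = "undefined_correlation")
})

test_that("peak measurement extracts sign and absolute lag in seconds", {
  w <- sine_wave(1, duration = 4)
  pk <- peak_measurement(cross_correlate(w, w))
  expect_identical(pk$sign, 1L)
  expect_identical(pk$d_max, 0)

  # half-period delay: anti-phase, and the smallest-|lag| tie-break gives 0
  y <- sine_wave(1, duration = 4, phase = pi)
  pk2 <- peak_measurement(cross_correlate(w, y))
  expect_identical(pk2$sign, -1L)
  expect_identical(pk2$lag, 0L)
  expect_identical(pk2$d_max, 0)

  # 5-sample delay at 25 fps = 0.20 s; oracle confirms. A multi-harmonic
  # pulse has a sharp autocorrelation, so the peak sits exactly at the shift.
  t <- (0:149) / 25
  p <- plaquesync:::cardiac_pulse(t, 1, 3)
  x5 <- p[6:125]
  y5 <- p[1:120]  # x delayed by 5 samples
  cc <- cross_correlate(wave(x5, 25), wave(y5, 25))
  pk3 <- peak_measurement(cc)
  expect_equal(pk3$d_max, 0.20)
  o <- oracle_peak(oracle_crosscorr(x5, y5), cc$lag)
  expect_equal(abs(o$lag) / 25, pk3$d_max)
})

test_that("synchronisation percentage counts positive peak signs", {
  expect_identical(synchronisation_percentage(rep(1, 6)), 100)
  expect_identical(synchronisation_percentage(c(rep(1, 8), rep(-1, 2))), 80)
  expect_equal(synchronisation_percentage(c(1, -1, 1, -1, 1, -1, 1)),
               100 * 4 / 7, tolerance = 1e-9)
  expect_equal(round(synchronisation_percentage(c(1, -1, 1, -1, 1, -1, 1)), 2),
               57.14)
  expect_error(synchronisation_percentage(numeric(0)), class = "empty_input")
  expect_error(synchronisation_percentage(c(1, 0)), class = "invalid_signs")
})

test_that("lag statistics match direct moment formulas", {
  s <- lag_statistics(rep(0.2, 5))
  expect_equal(unlist(s), c(max = 0.2, min = 0.2, mean = 0.2, median = 0.2,
                            stdev = 0, skewness = 0, kurtosis = 0))
  v <- c(0.0, 0.04, 0.08, 0.40)
  s2 <- lag_statistics(v)
  o <- oracle_stats(v)
  for (nm in names(o)) expect_equal(s2[[nm]], o[[nm]], tolerance = 1e-12)
  # symmetric set has zero skewness
  expect_equal(lag_statistics(c(0.1, 0.2, 0.3))$skewness, 0, tolerance = 1e-12)
  expect_error(lag_statistics(numeric(0)), class = "empty_input")
})

test_that("lag statistics agree with e1071's moment-based estimators", {
  skip_if_not_installed("e1071")
  set.seed(12)
  v <- abs(rnorm(40, 0.2, 0.1))
  s <- lag_statistics(v)
  expect_equal(s$skewness, e1071::skewness(v, type = 1), tolerance = 1e-12)
  expect_equal(s$kurtosis, e1071::kurtosis(v, type = 1), tolerance = 1e-12)
})

test_that("plaque features always assemble 24 named features", {
  spec <- cohort_spec(n = c(a = 2, b = 2), delay_mean = c(a = 0, b = 0.2),
                      delay_sd = c(a = 0, b = 0), seed = 3)
  coh <- generate_cohort(spec)
  feat_cols <- setdiff(names(coh), c("plaque", "label", "true_delay"))
  expect_identical(feat_cols, plaquesync:::cc_feature_names())
  expect_identical(length(feat_cols), 24L)
})

test_that("zero-delay synthetic plaques are fully synchronous; delays are recovered", {
  fs <- 25; t <- (0:124) / fs
  pulse <- function(tt) plaquesync:::cardiac_pulse(tt, 1, 3)
  # top and bottom amplitudes differ slightly so the plaque radial distance
  # (the CC1 input) is not degenerate at zero delay
  mk_traj <- function(roi, depth, delay, amp) {
    purrr::map(1:6, function(p) {
      tibble::tibble(roi = roi, pixel = p, frame = seq_along(t),
                     row = depth * 12 + amp * pulse(t - delay),
                     col = 8 * p + 3 * (pulse(t - delay) - pulse(-delay)))
    }) |> purrr::list_rbind()
  }
  wall <- wave(3 + 0.8 * pulse(t), fs, kind = "wall_diameter")

  f0 <- plaque_features(wall, mk_traj("PTS", 3.4, 0, 4.8),
                        mk_traj("PBS", 4.8, 0, 4.4))
  expect_identical(f0$sp_CC2, 100)
  expect_identical(f0$sp_CC3, 100)
  expect_identical(f0$mean_CC2, 0)
  expect_identical(f0$mean_CC3, 0)

  fd <- plaque_features(wall, mk_traj("PTS", 3.4, 0.2, 4.8),
                        mk_traj("PBS", 4.8, 0, 4.4))
  expect_lte(abs(fd$mean_CC2 - 0.2), 0.04)
  expect_lte(abs(fd$mean_CC3 - 0.2), 0.04)
})

test_that("windowed delay estimation recovers generator delays within one sample", {
  set.seed(55)
  errs <- vapply(1:30, function(i) {
    d <- runif(1, 0, 0.4)
    m <- motion_model(top_bottom_delay = d, fundamental_freq = runif(1, 0.8, 1.2),
                      noise_sd = 0.03, drift_amp = 0.2, seed = 5000 + i)
    pair <- generate_waveform_pair(m)
    abs(estimate_delay(pair$x, pair$y)$d_max - d)
  }, 0)
  expect_lte(mean(errs), 0.04)
})
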