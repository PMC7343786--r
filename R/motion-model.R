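#' Parametric model of pulsatile arterial tissue motion
#'
#' Describes the generative motion used by the synthetic-data module: a
#' periodic cardiac pulse (sum of `n_harmonics` cosines with 1/k amplitude
#' decay) driving radial and longitudinal tissue displacement, with a
#' configurable phase delay of the plaque top surface relative to the bottom
#' surface, a delay of the plaque relative to the adjacent wall, slow additive
#' baseline drift (breathing / transducer motion) and additive Gaussian noise.
#'
#' @param fundamental_freq Cardiac fundamental frequency in Hz. Resting heart
#'   rates put this around 0.7-1.7 Hz; the default 1.1 Hz is 66 bpm.
#' @param n_harmonics Number of harmonics in the pulse shape.
#' @param radial_amp Radial displacement amplitude in mm.
#' @param longitudinal_amp Longitudinal displacement amplitude in mm.
#' @param top_bottom_delay Delay, in seconds, of the plaque top surface (PTS)
#'   motion relative to the bottom surface (PBS). This is the ground-truth
#'   phase shift recovered by the CC2/CC3 pipeline.
#' @param wall_plaque_delay Delay, in seconds, of the plaque motion relative
#'   to the adjacent-wall motion (probed by CC1).
#' @param drift_amp Amplitude in mm of a slow sinusoidal baseline drift.
#' @param drift_freq Drift frequency in Hz; must stay below 0.3 Hz so the
#'   0.6 Hz high-pass removes it.
#' @param noise_sd Standard deviation in mm of additive white noise on each
#'   displacement sample.
#' @param duration Recording duration in seconds (default 5 s, room for a
#'   settled post-filter analysis window); at least three cardiac
#'   cycles are required.
#' @param frame_rate Frame rate in frames/s (default 25, typical of B-mode
#'   cine loops).
#' @param seed Optional integer seed; all randomness in generators consuming
#'   the model flows through it.
#'
#' @return A `motion_model` object (a validated list of the above fields).
#' @examples
#' m <- motion_model(top_bottom_delay = 0.2, seed = 42)
#' pair <- generate_waveform_pair(m)
#' pair$delay
#' @export
motion_model <- function(fundamental_freq = 1.1, n_harmonics = 3,
                         radial_amp = 0.4, longitudinal_amp = 0.25,
                         top_bottom_delay = 0, wall_plaque_delay = 0,
                         drift_amp = 0, drift_freq = 0.1, noise_sd = 0.02,
                         duration = 5, frame_rate = 25, seed = NULL) {
  m <- list(fundamental_freq = fundamental_freq, n_harmonics = as.integer(n_harmonics),
            radial_amp = radial_amp, longitudinal_amp = longitudinal_amp,
            top_bottom_delay = top_bottom_delay, wall_plaque_delay = wall_plaque_delay,
            drift_amp = drift_amp, drift_freq = drift_freq, noise_sd = noise_sd,
            duration = duration, frame_rate = frame_rate, seed = seed)
  validate_motion_model(m)
  structure(m, class = "motion_model")
}

validate_motion_model <- function(m) {
  for (f in c("fundamental_freq", "radial_amp", "longitudinal_amp",
              "top_bottom_delay", "wall_plaque_delay", "drift_amp",
              "drift_freq", "noise_sd", "duration", "frame_rate")) {
    if (!is_scalar_number(m[[f]])) {
      stop_plq(sprintf("motion model field `%s` must be a finite number", f),
               "invalid_model")
    }
  }
  if (m$fundamental_freq <= 0 || m$n_harmonics < 1) {
    stop_plq("fundamental frequency and harmonic count must be positive",
             "invalid_model")
  }
  if (m$drift_freq >= 0.3) {
    stop_plq("drift frequency must stay below 0.3 Hz (slow baseline motion)",
             "invalid_model")
  }
  if (m$fundamental_freq <= m$drift_freq) {
    stop_plq("cardiac fundamental must exceed the drift frequency", "invalid_model")
  }
  if (m$frame_rate <= 2 * m$fundamental_freq * m$n_harmonics) {
    stop_plq("frame rate must exceed twice the highest harmonic frequency",
             "invalid_model")
  }
  if (m$duration < 3 / m$fundamental_freq) {
    stop_plq("duration must cover at least three cardiac cycles", "invalid_model")
  }
  invisible(m)
}

# Periodic cardiac pulse: sum of K cosines with 1/k decay, scaled to peak 1
# at t = 0.
cardiac_pulse <- function(t, fundamental_freq, n_harmonics) {
  k <- seq_len(n_harmonics)
  s <- numeric(length(t))
  for (kk in k) s <- s + cos(2 * pi * kk * fundamental_freq * t) / kk
  s / sum(1 / k)
}

model_times <- function(model) {
  n <- round(model$duration * model$frame_rate)
  (seq_len(n) - 1) / model$frame_rate
}

# One drift + noise realisation of the model's nuisance terms.
nuisance_terms <- function(model, t) {
  drift <- if (model$drift_amp > 0) {
    model$drift_amp * sin(2 * pi * model$drift_freq * t + runif(1, 0, 2 * pi))
  } else {
    rep(0, length(t))
  }
  noise <- if (model$noise_sd > 0) rnorm(length(t), 0, model$noise_sd) else rep(0, length(t))
  drift + noise
}

#' Generate a delayed pair of pulsatile displacement waveforms
#'
#' Produces a "bottom surface" waveform and a "top surface" waveform delayed
#' by `top_bottom_delay`, each with its own drift and noise realisation, plus
#' the ground-truth delay. These emulate the radial (or, with
#' `axis = "longitudinal"`, the longitudinal) displacement of a vertical
#' PTS-PBS pixel pair.
#'
#' @param model A [motion_model()].
#' @param axis `"radial"` (uses `radial_amp`) or `"longitudinal"`.
#' @return A list with elements `x` (PBS-side [wave()]), `y` (PTS-side wave,
#'   delayed), and `delay` (the ground-truth delay in seconds).
#' @export
generate_waveform_pair <- function(model, axis = c("radial", "longitudinal")) {
  validate_motion_model(model)
  axis <- match.arg(axis)
  amp <- if (axis == "radial") model$radial_amp else model$longitudinal_amp
  with_rng(model$seed, {
    t <- model_times(model)
    base <- function(tt) amp * cardiac_pulse(tt, model$fundamental_freq, model$n_harmonics)
    x <- base(t) + nuisance_terms(model, t)
    y <- base(t - model$top_bottom_delay) + nuisance_terms(model, t)
    list(x = wave(x, model$frame_rate, kind = paste0("PBS_", axis)),
         y = wave(y, model$frame_rate, kind = paste0("PTS_", axis)),
         delay = model$top_bottom_delay)
  })
}
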