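#' Specification of a synthetic labelled cohort
#'
#' Describes a two-or-more-group cohort of synthetic plaques for testing the
#' association pipeline. Two generation modes are supported:
#' \describe{
#'   \item{waveform mode}{(`delay_mean`/`delay_sd` given) each plaque gets a
#'     top-bottom delay drawn from its group's Normal distribution (censored
#'     at 0, phase shifts being non-negative), and its 24 features are
#'     computed by running synthetic PTS/PBS pixel-pair waveforms through the
#'     real filtering/windowing/cross-correlation pipeline;}
#'   \item{feature mode}{(`feature_mean`/`feature_sd` given) features are
#'     drawn directly from per-group Normal distributions -- useful for
#'     classifier sanity checks (e.g. deterministic, separable cohorts with
#'     `sd = 0`).}
#' }
#'
#' @param n Named integer vector of per-group plaque counts (>= 2 groups,
#'   >= 2 each); names are the group labels.
#' @param delay_mean,delay_sd Named numeric vectors (same names as `n`):
#'   per-group mean and standard deviation, in seconds, of the plaque
#'   top-bottom delay.
#' @param feature_mean,feature_sd Named lists of named numeric vectors: per
#'   group, the mean and sd of each generated feature.
#' @param n_pairs Pixel pairs simulated per plaque in waveform mode.
#' @param pair_jitter_sd Per-pair delay jitter (s) around the plaque delay.
#' @param fundamental_range Range of cardiac fundamental frequencies (Hz)
#'   sampled per plaque; the default 0.8-1.2 Hz (48-72 bpm) keeps delays up
#'   to ~0.4 s below half a cardiac period, where lags are identifiable.
#' @param noise_sd Additive waveform noise (mm) in waveform mode.
#' @param seed Integer seed; same seed, same cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n, delay_mean = NULL, delay_sd = NULL,
                        feature_mean = NULL, feature_sd = NULL,
                        n_pairs = 12, pair_jitter_sd = 0.02,
                        fundamental_range = c(0.8, 1.2), noise_sd = 0.03,
                        seed = NULL) {
  if (length(n) < 2 || is.null(names(n)) || any(!nzchar(names(n)))) {
    stop_plq("`n` must be a named vector with at least two groups", "invalid_cohort_spec")
  }
  if (any(n < 2)) {
    stop_plq("each group needs at least 2 plaques", "invalid_cohort_spec")
  }
  mode <- if (!is.null(delay_mean)) "waveforms" else "features"
  if (mode == "waveforms") {
    if (is.null(delay_sd) || !setequal(names(delay_mean), names(n)) ||
        !setequal(names(delay_sd), names(n))) {
      stop_plq("`delay_mean` and `delay_sd` must name every group", "invalid_cohort_spec")
    }
    if (any(delay_sd < 0)) {
      stop_plq("degenerate delay sd < 0", "invalid_cohort_spec")
    }
  } else {
    if (is.null(feature_mean) || is.null(feature_sd)) {
      stop_plq("give either delay_mean/delay_sd or feature_mean/feature_sd",
               "invalid_cohort_spec")
    }
    if (any(unlist(feature_sd) < 0)) {
      stop_plq("degenerate feature sd < 0", "invalid_cohort_spec")
    }
  }
  structure(list(n = n, mode = mode, delay_mean = delay_mean, delay_sd = delay_sd,
                 feature_mean = feature_mean, feature_sd = feature_sd,
                 n_pairs = as.integer(n_pairs), pair_jitter_sd = pair_jitter_sd,
                 fundamental_range = fundamental_range, noise_sd = noise_sd,
                 seed = seed),
            class = "cohort_spec")
}

# One synthetic plaque in waveform mode: build PTS/PBS pixel-pair
# trajectories (positions in px) plus a wall-diameter wave, then run the
# real measurement pipeline.
simulate_plaque_features <- function(delay, spec, spacing = 12) {
  f0 <- runif(1, spec$fundamental_range[1], spec$fundamental_range[2])
  fs <- 25
  duration <- 4
  t <- (seq_len(round(duration * fs)) - 1) / fs
  a <- 0.4; a_l <- 0.25
  pulse <- function(tt) cardiac_pulse(tt, f0, 3)
  half_period <- 0.5 / f0
  delay <- clamp(delay, 0, 0.9 * half_period)

  noise <- function() rnorm(length(t), 0, spec$noise_sd)
  mk_traj <- function(base_depth, delays) {
    purrr::map(seq_along(delays), function(j) {
      l <- (a_l * pulse(t - delays[j]) + noise()) * spacing
      tibble(pixel = j, frame = seq_along(t),
             row = (base_depth + a * pulse(t - delays[j]) + noise()) * spacing,
             # anchored so frame-1 columns pair exactly across interfaces
             col = j * 8 + l - l[1])
    }) |> list_rbind() |> mutate(roi = "sim", .before = 1)
  }
  pair_delays <- pmax(0, delay + rnorm(spec$n_pairs, 0, spec$pair_jitter_sd))
  pts <- mk_traj(3.6, pair_delays)
  pbs <- mk_traj(4.6, rep(0, spec$n_pairs))
  wall <- wave(3 + 2 * a * pulse(t) + noise(), fs, kind = "wall_diameter")
  plaque_features(wall, pts, pbs, spacing = spacing)
}

#' Generate a labelled synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with a `plaque` id, a `label` factor, a `true_delay`
#'   column in waveform mode, and the feature columns.
#' @examples
#' spec <- cohort_spec(n = c(lo = 4, hi = 4),
#'                     delay_mean = c(lo = 0.1, hi = 0.3),
#'                     delay_sd = c(lo = 0.05, hi = 0.05), seed = 1)
#' generate_cohort(spec)[, 1:5]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_rng(spec$seed, {
    groups <- names(spec$n)
    rows <- purrr::map(groups, function(g) {
      ng <- spec$n[[g]]
      if (spec$mode == "waveforms") {
        delays <- pmax(0, rnorm(ng, spec$delay_mean[[g]], spec$delay_sd[[g]]))
        feats <- purrr::map(delays, simulate_plaque_features, spec = spec) |>
          list_rbind()
        mutate(feats, label = g, true_delay = delays, .before = 1)
      } else {
        mu <- spec$feature_mean[[g]]
        sg <- spec$feature_sd[[g]]
        vals <- purrr::map(names(mu), function(f) rnorm(ng, mu[[f]], sg[[f]]))
        names(vals) <- names(mu)
        mutate(as_tibble(vals), label = g, .before = 1)
      }
    }) |> list_rbind()
    rows |>
      mutate(plaque = row_number(), .before = 1) |>
      mutate(label = factor(.data$label, levels = groups))
  })
}
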