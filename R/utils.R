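# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the global stream untouched.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Seeds for sub-tasks derived from one master seed; kept inside 32-bit range.
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_plq <- function(msg, class) abort(msg, class = c(class, "plaquesync_error"))

# Raw periodogram of a demeaned series: |FFT|^2 / N at the Fourier frequencies
# below Nyquist (frequency 0 excluded).
periodogram <- function(values, frame_rate) {
  x <- values - mean(values)
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  tibble(frequency = k * frame_rate / n, power = p[k + 1L])
}
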