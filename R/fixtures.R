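#' Synthetic pulse trace configuration
#'
#' Describes a quasi-periodic blood-volume-pulse-like waveform with the
#' disturbance classes seen in camera photoplethysmography: slow
#' illumination drift, sparse motion-artifact transients, and broadband
#' sensor noise.  The waveform is a fundamental sinusoid at the (possibly
#' time-varying) heart-rate frequency plus geometrically decaying
#' harmonics, which captures the asymmetry of a pulse wave without
#' committing to a physiological template.
#'
#' @param duration_s trace length in seconds.
#' @param fps frames per second.
#' @param hr_bpm heart rate in beats/minute: a scalar, or a two-column
#'   `data.frame(time_s, hr_bpm)` interpolated piecewise-linearly.  Every
#'   schedule point must lie in [42, 180] bpm (the 0.7-3 Hz pulse band).
#' @param drift_amplitude amplitude of the sinusoidal baseline drift, in
#'   units of the pulse fundamental (amplitude 1).
#' @param drift_period_s drift period in seconds.
#' @param artifact_rate motion-artifact events per minute (Poisson).
#' @param artifact_amplitude peak amplitude of each transient, pulse units.
#' @param artifact_width transient width in frames.
#' @param noise_sigma additive white Gaussian noise sd, pulse units.
#' @param harmonics number of harmonics above the fundamental.
#' @param harmonic_decay relative amplitude ratio between consecutive
#'   harmonics (default 0.5: amplitudes 1, 0.5, 0.25, ...).
#' @param baseline constant offset mimicking mean pixel intensity.
#' @param seed integer; fully determines the generated trace.
#' @return a `pulse_sim_config` list.
#' @export
pulse_sim_config <- function(duration_s = 60, fps = 30, hr_bpm = 72,
                             drift_amplitude = 0, drift_period_s = 30,
                             artifact_rate = 0, artifact_amplitude = 3,
                             artifact_width = 5, noise_sigma = 0,
                             harmonics = 2, harmonic_decay = 0.5,
                             baseline = 100, seed = 1) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(fps, "fps", positive = TRUE)
  if (is.data.frame(hr_bpm)) {
    stop_if(!all(c("time_s", "hr_bpm") %in% names(hr_bpm)),
            "'hr_bpm' schedule needs columns 'time_s' and 'hr_bpm'")
    stop_if(any(hr_bpm$hr_bpm < 42 | hr_bpm$hr_bpm > 180),
            "'hr_bpm' schedule points must lie in [42, 180] bpm")
  } else {
    check_scalar(hr_bpm, "hr_bpm", positive = TRUE)
    stop_if(hr_bpm < 42 || hr_bpm > 180,
            "'hr_bpm' must lie in [42, 180] bpm")
  }
  check_scalar(drift_amplitude, "drift_amplitude")
  check_scalar(drift_period_s, "drift_period_s", positive = TRUE)
  check_scalar(artifact_rate, "artifact_rate")
  stop_if(artifact_rate < 0, "'artifact_rate' must be >= 0")
  check_scalar(artifact_amplitude, "artifact_amplitude")
  check_scalar(artifact_width, "artifact_width", positive = TRUE,
               integerish = TRUE)
  check_scalar(noise_sigma, "noise_sigma")
  stop_if(noise_sigma < 0, "'noise_sigma' must be >= 0")
  check_scalar(harmonics, "harmonics", integerish = TRUE)
  stop_if(harmonics < 0, "'harmonics' must be >= 0")
  check_scalar(harmonic_decay, "harmonic_decay", positive = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "pulse_sim_config")
}

#' Simulate a pulse-like color trace with known heart rate
#'
#' Deterministic given the config (seed included).  The instantaneous
#' heart-rate schedule used to drive the oscillator is returned alongside
#' the trace so recovery error is computable against ground truth.
#'
#' @param cfg a [pulse_sim_config()].
#' @return a `pulse_sim` list with elements `trace` ([color_trace()]),
#'   `hr_bpm` (per-frame ground-truth heart rate), `clean` (waveform before
#'   drift/artifacts/noise) and `config`.
#' @export
simulate_pulse_trace <- function(cfg) {
  stopifnot(inherits(cfg, "pulse_sim_config"))
  n <- round(cfg$duration_s * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  hr <- if (is.data.frame(cfg$hr_bpm)) {
    stats::approx(cfg$hr_bpm$time_s, cfg$hr_bpm$hr_bpm, xout = t,
                  rule = 2)$y
  } else rep(cfg$hr_bpm, n)
  freq <- hr / 60
  phase <- 2 * pi * cumsum(freq) / cfg$fps
  amp <- cfg$harmonic_decay^(0:cfg$harmonics)
  clean <- rowSums(vapply(seq_along(amp),
                          function(h) amp[h] * sin(h * phase), numeric(n)))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  x <- clean + cfg$baseline +
    cfg$drift_amplitude * sin(2 * pi * t / cfg$drift_period_s)
  n_events <- stats::rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
  if (n_events > 0) {
    centers <- sort(ceiling(stats::runif(n_events) * n))
    signs <- sample(c(-1, 1), n_events, replace = TRUE)
    w <- cfg$artifact_width
    bump <- sin(pi * seq_len(w) / (w + 1))  # half-sine transient
    for (e in seq_len(n_events)) {
      i0 <- centers[e] - (w %/% 2)
      idx <- i0:(i0 + w - 1)
      ok <- idx >= 1 & idx <= n
      x[idx[ok]] <- x[idx[ok]] + signs[e] * cfg$artifact_amplitude * bump[ok]
    }
  }
  if (cfg$noise_sigma > 0) x <- x + stats::rnorm(n, sd = cfg$noise_sigma)
  structure(list(trace = color_trace(x, fps = cfg$fps),
                 hr_bpm = hr, clean = clean, config = cfg),
            class = "pulse_sim")
}

#' Low-rank plus sparse test-matrix configuration
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param rank rank of the low-rank part (must be < min(n_rows, n_cols)).
#' @param sparse_fraction fraction of entries corrupted (in [0, 0.5)).
#' @param sparse_magnitude corruption entries are uniform on
#'   +/- `sparse_magnitude`.
#' @param seed integer seed.
#' @return a `lowrank_sim_config` list.
#' @export
lowrank_sim_config <- function(n_rows, n_cols, rank, sparse_fraction,
                               sparse_magnitude = 1, seed = 1) {
  check_scalar(n_rows, "n_rows", positive = TRUE, integerish = TRUE)
  check_scalar(n_cols, "n_cols", positive = TRUE, integerish = TRUE)
  check_scalar(rank, "rank", integerish = TRUE)
  stop_if(rank < 0, "'rank' must be >= 0")
  stop_if(rank >= min(n_rows, n_cols),
          "'rank' must be < min(n_rows, n_cols)")
  check_scalar(sparse_fraction, "sparse_fraction")
  stop_if(sparse_fraction < 0 || sparse_fraction >= 0.5,
          "'sparse_fraction' must be in [0, 0.5)")
  check_scalar(sparse_magnitude, "sparse_magnitude")
  check_scalar(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "lowrank_sim_config")
}

#' Simulate an exactly low-rank matrix with sparse corruption
#'
#' Standard robust-PCA test protocol: `A_true = P %*% t(Q)` with Gaussian
#' factors (rank exactly `rank`), and `E_true` uniform on
#' +/- `sparse_magnitude` over a uniformly random support of
#' `round(sparse_fraction * n_rows * n_cols)` entries.
#'
#' @param cfg a [lowrank_sim_config()].
#' @return list with `X` (= `A_true + E_true` exactly), `A_true`, `E_true`.
#' @export
simulate_lowrank_sparse <- function(cfg) {
  stopifnot(inherits(cfg, "lowrank_sim_config"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  m <- cfg$n_rows; n <- cfg$n_cols; r <- cfg$rank
  A <- if (r > 0) {
    matrix(stats::rnorm(m * r), m, r) %*% t(matrix(stats::rnorm(n * r), n, r)) / sqrt(r)
  } else matrix(0, m, n)
  E <- matrix(0, m, n)
  k <- round(cfg$sparse_fraction * m * n)
  if (k > 0) {
    support <- sample.int(m * n, k)
    E[support] <- stats::runif(k, -cfg$sparse_magnitude, cfg$sparse_magnitude)
  }
  list(X = A + E, A_true = A, E_true = E)
}

#' Synthetic skin/background test image
#'
#' A flat image with one rectangular patch of "skin" color on a uniform
#' background, used to exercise the skin-pixel classifier pixelwise.
#'
#' @param width,height image size in pixels.
#' @param skin_rect integer vector `c(row0, col0, row1, col1)` (1-based,
#'   inclusive) of the skin patch; must lie inside the image.
#' @param skin_rgb,background_rgb length-3 RGB triples on the 0-255 scale.
#' @return a `height x width x 3` numeric array on the 0-255 scale.
#' @export
synth_skin_image <- function(width, height, skin_rect, skin_rgb,
                             background_rgb = c(20, 20, 20)) {
  check_scalar(width, "width", positive = TRUE, integerish = TRUE)
  check_scalar(height, "height", positive = TRUE, integerish = TRUE)
  stop_if(length(skin_rect) != 4 || any(skin_rect != round(skin_rect)),
          "'skin_rect' must be c(row0, col0, row1, col1), integers")
  r <- as.integer(skin_rect)
  stop_if(r[1] < 1 || r[2] < 1 || r[3] > height || r[4] > width ||
            r[1] > r[3] || r[2] > r[4],
          "'skin_rect' out of image bounds")
  stop_if(length(skin_rgb) != 3 || length(background_rgb) != 3,
          "colors must be RGB triples")
  img <- array(rep(background_rgb, each = height * width),
               dim = c(height, width, 3))
  for (ch in 1:3) img[r[1]:r[3], r[2]:r[4], ch] <- skin_rgb[ch]
  img
}
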