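#' Preprocessing configuration
#'
#' Parameters of the coarse-denoising chain applied before singular
#' spectrum analysis: smoothness-prior detrending, normalization,
#' moving-average smoothing, and ensemble empirical mode decomposition
#' (EEMD) with spectral selection of the pulse-band mode.
#'
#' @param detrend_lambda regularization weight of the smoothness-prior
#'   detrender.  The default 300 places the effective high-pass cutoff
#'   near 0.36 Hz at 30 fps, below the 0.7 Hz floor of the pulse band.
#' @param ma_window moving-average width in frames (odd, >= 3).
#' @param eemd_noise_std sd of the white noise added per EEMD ensemble
#'   member, as a fraction of the sd of the input series.
#' @param eemd_ensembles ensemble size.
#' @param eemd_max_imf maximum number of intrinsic mode functions.
#' @param eemd_sd_tol sifting stop threshold (sum-of-squares criterion).
#' @param eemd_max_sift maximum sifting passes per mode.
#' @param hr_band pulse frequency band in Hz used for mode selection.
#' @param use_eemd logical; FALSE bypasses EEMD (ablation switch) so the
#'   smoothed series is passed through unchanged.
#' @return a `preproc_config` list.
#' @export
preproc_config <- function(detrend_lambda = 300, ma_window = 5,
                           eemd_noise_std = 0.05, eemd_ensembles = 100,
                           eemd_max_imf = 10, eemd_sd_tol = 0.2,
                           eemd_max_sift = 10, hr_band = c(0.7, 3),
                           use_eemd = TRUE) {
  check_scalar(detrend_lambda, "detrend_lambda")
  stop_if(detrend_lambda < 0, "'detrend_lambda' must be >= 0")
  check_scalar(ma_window, "ma_window", positive = TRUE, integerish = TRUE)
  stop_if(ma_window %% 2 == 0 || ma_window < 3,
          "'ma_window' must be odd and >= 3")
  check_scalar(eemd_noise_std, "eemd_noise_std")
  stop_if(eemd_noise_std < 0, "'eemd_noise_std' must be >= 0")
  check_scalar(eemd_ensembles, "eemd_ensembles", positive = TRUE,
               integerish = TRUE)
  check_scalar(eemd_max_imf, "eemd_max_imf", positive = TRUE,
               integerish = TRUE)
  check_scalar(eemd_sd_tol, "eemd_sd_tol", positive = TRUE)
  check_scalar(eemd_max_sift, "eemd_max_sift", positive = TRUE,
               integerish = TRUE)
  stop_if(length(hr_band) != 2 || hr_band[1] <= 0 || hr_band[1] >= hr_band[2],
          "'hr_band' must be c(low, high) with 0 < low < high")
  stop_if(!is.logical(use_eemd) || length(use_eemd) != 1,
          "'use_eemd' must be TRUE or FALSE")
  structure(as.list(environment()), class = "preproc_config")
}

#' Smoothness-prior detrending
#'
#' Removes the low-frequency trend by subtracting the regularized fit
#' `trend = (I + lambda^2 t(D2) %*% D2)^{-1} x`, where `D2` is the
#' second-difference operator.  Acts as a high-pass filter whose cutoff
#' decreases as `lambda` grows; `lambda = 0` returns all zeros (the trend
#' is the signal itself).
#'
#' @param x numeric series (length >= 3, finite).
#' @param lambda smoothing parameter (>= 0, dimensionless).
#' @return the detrended series, same length as `x`.
#' @export
detrend_smoothness_prior <- function(x, lambda = 300) {
  check_series(x, "x", min_len = 3L)
  check_scalar(lambda, "lambda")
  stop_if(lambda < 0, "'lambda' must be >= 0")
  if (lambda == 0) return(numeric(length(x)))
  n <- length(x)
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  trend <- Matrix::solve(Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2),
                         x)
  x - as.numeric(trend)
}

#' Standardize a series to zero mean, unit standard deviation
#'
#' @param x numeric series with nonzero variance.
#' @return the standardized series.
#' @export
normalize_series <- function(x) {
  check_series(x, "x")
  s <- stats::sd(x)
  stop_if(s == 0, "'x' has zero variance; cannot normalize")
  (x - mean(x)) / s
}

#' Centered moving average with shrinking edge windows
#'
#' `y[i]` is the mean of `x` over the symmetric window of `window` frames
#' centered at `i`; near the edges the window shrinks so the output keeps
#' the input length.
#'
#' @param x numeric series, length >= `window`.
#' @param window odd window width in frames (default 5).
#' @return smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window = 5) {
  check_scalar(window, "window", positive = TRUE, integerish = TRUE)
  stop_if(window %% 2 == 0, "'window' must be odd")
  check_series(x, "x", min_len = as.integer(window))
  n <- length(x)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Ensemble empirical mode decomposition
#'
#' Averages the intrinsic mode functions (IMFs) of `eemd_ensembles` EMD
#' runs, each on the input perturbed by white noise of sd
#' `eemd_noise_std * sd(x)`.  IMFs are aligned by index across members;
#' members that terminate early contribute zeros to the missing indices.
#' The returned residual is the ensemble-averaged sifting residual, so
#' `rowSums(imfs) + residual` reconstructs the input up to the averaged
#' injected noise (relative RMS about `eemd_noise_std / sqrt(ensembles)`).
#'
#' @param x numeric series, length >= 16.
#' @param fps sampling rate in frames/second (carried into the result).
#' @param cfg a [preproc_config()].
#' @param seed optional integer; when given, the ensemble noise is drawn
#'   from this seed and the caller's RNG state is restored afterwards.
#' @return an `imf_set` list with `imfs` (N x k matrix, columns ordered
#'   high to low frequency), `residual`, `fps`.
#' @export
eemd <- function(x, fps, cfg = preproc_config(), seed = NULL) {
  check_series(x, "x", min_len = 16L)
  check_scalar(fps, "fps", positive = TRUE)
  stopifnot(inherits(cfg, "preproc_config"))
  n <- length(x)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sigma <- cfg$eemd_noise_std * stats::sd(x)
  noise <- if (sigma > 0) {
    matrix(stats::rnorm(n * cfg$eemd_ensembles, sd = sigma),
           n, cfg$eemd_ensembles)
  } else matrix(0, n, 1)
  res <- .eemd_c(x, noise, cfg$eemd_max_imf, cfg$eemd_sd_tol,
                 cfg$eemd_max_sift)
  if (res$n_imf == 0) {
    # fewer than 2 extrema: the signal is its own residual
    return(structure(list(imfs = matrix(0, n, 0), residual = x, fps = fps),
                     class = "imf_set"))
  }
  structure(list(imfs = res$imfs, residual = as.numeric(res$residual),
                 fps = fps),
            class = "imf_set")
}

#' Single (non-ensemble) empirical mode decomposition
#'
#' The deterministic sifting underlying [eemd()]; exposed for inspection
#' and property checks of the mode definition.
#'
#' @inheritParams eemd
#' @return an `imf_set` list.
#' @export
emd <- function(x, fps, cfg = preproc_config()) {
  check_series(x, "x", min_len = 16L)
  check_scalar(fps, "fps", positive = TRUE)
  res <- .emd_c(x, cfg$eemd_max_imf, cfg$eemd_sd_tol, cfg$eemd_max_sift)
  if (res$n_imf == 0) {
    return(structure(list(imfs = matrix(0, length(x), 0), residual = x,
                          fps = fps), class = "imf_set"))
  }
  structure(list(imfs = res$imfs, residual = as.numeric(res$residual),
                 fps = fps),
            class = "imf_set")
}

# Magnitude spectrum on a zero-padded grid (next power of two >= pad_min * N).
magnitude_spectrum <- function(x, fps, pad_min = 8) {
  n <- length(x)
  nfft <- 2^ceiling(log2(pad_min * n))
  mag <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))
  half <- seq_len(nfft %/% 2 + 1)
  list(freq = (half - 1) * fps / nfft, mag = mag[half])
}

#' Select the IMF dominating the pulse band
#'
#' Computes each mode's zero-padded magnitude spectrum and returns the mode
#' whose largest in-band magnitude is the greatest across modes (ties break
#' to the lower index, i.e. the higher-frequency mode).
#'
#' @param imf_set an `imf_set` from [eemd()] or [emd()].
#' @param hr_band pulse band in Hz.
#' @return list with `series` (the selected IMF), `index`, and
#'   `band_peaks` (each mode's maximum in-band magnitude).
#' @export
select_imf_by_band <- function(imf_set, hr_band = c(0.7, 3)) {
  stopifnot(inherits(imf_set, "imf_set"))
  k <- ncol(imf_set$imfs)
  stop_if(k < 1, "no IMFs to select from")
  peaks <- numeric(k)
  for (i in seq_len(k)) {
    sp <- magnitude_spectrum(imf_set$imfs[, i], imf_set$fps)
    inb <- sp$freq >= hr_band[1] & sp$freq <= hr_band[2]
    peaks[i] <- if (any(inb)) max(sp$mag[inb]) else 0
  }
  stop_if(max(peaks) <= .Machine$double.eps,
          "no IMF has in-band energy; consider passing the raw series through")
  idx <- which.max(peaks)
  list(series = imf_set$imfs[, idx], index = idx, band_peaks = peaks)
}

#' Run the full preprocessing chain on a trace
#'
#' Fixed order: detrend, normalize, moving average, then (unless disabled)
#' EEMD with in-band mode selection.
#'
#' @param trace a [color_trace()] (or bare numeric series plus `fps`).
#' @param fps sampling rate; taken from the trace when omitted.
#' @param cfg a [preproc_config()].
#' @param seed optional seed forwarded to [eemd()].
#' @param verbose log each stage's output RMS to stderr.
#' @return list with `series` (preprocessed signal), `smoothed` (the
#'   series before EEMD), and `imf_index` (NA when EEMD is bypassed).
#' @export
preprocess_trace <- function(trace, fps = NULL, cfg = preproc_config(),
                             seed = NULL, verbose = FALSE) {
  if (inherits(trace, "color_trace")) {
    x <- trace$values
    if (is.null(fps)) fps <- trace$fps
  } else {
    x <- trace
    stop_if(is.null(fps), "'fps' is required for a bare series")
  }
  rms <- function(v) sqrt(mean(v^2))
  log_stage <- function(stage, v) {
    if (verbose) message(sprintf("%-14s rms %.4g", stage, rms(v)))
  }
  log_stage("input", x)
  y <- detrend_smoothness_prior(x, cfg$detrend_lambda)
  log_stage("detrend", y)
  y <- normalize_series(y)
  y <- moving_average(y, cfg$ma_window)
  log_stage("smooth", y)
  if (!cfg$use_eemd) {
    return(list(series = y, smoothed = y, imf_index = NA_integer_))
  }
  modes <- eemd(y, fps, cfg, seed = seed)
  if (ncol(modes$imfs) == 0) {
    return(list(series = y, smoothed = y, imf_index = NA_integer_))
  }
  sel <- select_imf_by_band(modes, cfg$hr_band)
  log_stage(sprintf("eemd (IMF %d)", sel$index), sel$series)
  list(series = sel$series, smoothed = y, imf_index = sel$index)
}
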