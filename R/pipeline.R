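#' Analysis-window configuration
#'
#' Heart rate is read out per sliding window of `window_seconds`, advanced
#' by `step_seconds` (30 s / 1 s defaults); the windowed spectrum is
#' zero-padded by `fft_pad_factor` so the bin width at 30 s windows is
#' about 0.22 bpm.
#'
#' @param window_seconds window length in seconds (must cover at least two
#'   periods of the slowest in-band pulse).
#' @param step_seconds window advance in seconds (<= window_seconds).
#' @param hr_band pulse frequency band in Hz.
#' @param fft_pad_factor zero-padding multiple for the readout FFT.
#' @return a `window_config` list.
#' @export
window_config <- function(window_seconds = 30, step_seconds = 1,
                          hr_band = c(0.7, 3), fft_pad_factor = 8) {
  check_scalar(window_seconds, "window_seconds", positive = TRUE)
  check_scalar(step_seconds, "step_seconds", positive = TRUE)
  stop_if(length(hr_band) != 2 || hr_band[1] <= 0 || hr_band[1] >= hr_band[2],
          "'hr_band' must be c(low, high) with 0 < low < high")
  stop_if(window_seconds < 2 / hr_band[1],
          "'window_seconds' must cover two periods of the band floor")
  stop_if(step_seconds > window_seconds,
          "'step_seconds' must be <= 'window_seconds'")
  check_scalar(fft_pad_factor, "fft_pad_factor", positive = TRUE)
  structure(list(window_seconds = window_seconds,
                 step_seconds = step_seconds, hr_band = hr_band,
                 fft_pad_factor = fft_pad_factor),
            class = "window_config")
}

#' Spectral-peak heart rate of a series
#'
#' Returns `60 *` the frequency of the largest magnitude-spectrum bin
#' inside the pulse band, on a zero-padded FFT grid.
#'
#' @param x numeric series (at least 2 s of samples).
#' @param fps sampling rate in frames/second.
#' @param hr_band pulse band in Hz.
#' @param pad_factor zero-padding multiple.
#' @return heart rate in beats/minute.
#' @export
estimate_hr_fft <- function(x, fps, hr_band = c(0.7, 3), pad_factor = 8) {
  check_series(x, "x")
  check_scalar(fps, "fps", positive = TRUE)
  stop_if(length(x) < 2 * fps, "'x' must span at least 2 seconds")
  sp <- magnitude_spectrum(x, fps, pad_factor)
  inb <- which(sp$freq >= hr_band[1] & sp$freq <= hr_band[2])
  stop_if(length(inb) == 0, "no FFT bin inside the pulse band")
  stop_if(max(sp$mag[inb]) <= .Machine$double.eps * length(x),
          "no spectral peak inside the pulse band")
  60 * sp$freq[inb[which.max(sp$mag[inb])]]
}

#' Windowed heart-rate series container
#'
#' @param time window-center timestamps in seconds.
#' @param hr_bpm per-window heart rate, beats/minute.
#' @param flag per-window status marker ("ok", "ealm_fallback",
#'   "select_fallback", ...).
#' @return a data.frame of class `hr_series`.
#' @export
hr_series <- function(time, hr_bpm, flag = "ok") {
  stop_if(length(time) != length(hr_bpm), "'time'/'hr_bpm' length mismatch")
  structure(data.frame(time = time, hr_bpm = hr_bpm,
                       flag = rep_len(flag, length(time))),
            class = c("hr_series", "data.frame"))
}

window_starts <- function(n, fps, wcfg) {
  win <- round(wcfg$window_seconds * fps)
  step <- round(wcfg$step_seconds * fps)
  stop_if(n < win, "trace shorter than one analysis window")
  seq(1L, n - win + 1L, by = step)
}

# One window through the LA-SSA chain; returns the three readouts plus
# diagnostics.  `pre` is the preprocess_trace() result for the window.
lassa_window <- function(pre, fps, embed, ealm_cfg, sel_cfg, wcfg) {
  flag <- "ok"
  L <- round(embed$window_seconds * fps)
  X <- build_trajectory(pre$series, L)
  decomp <- ssa_decompose(X)
  split <- ealm_decompose(X, ealm_cfg)
  if (!split$converged) {
    # fallback: keep the leading singular values holding 90% of the total
    flag <- "ealm_fallback"
    s <- which(cumsum(decomp$values) / sum(decomp$values) >= 0.9)[1]
  } else {
    s <- split$s
  }
  s <- min(max(s, 1L), decomp$d)
  scores <- select_components(decomp, s, sel_cfg, fps)
  if (scores$fallback && flag == "ok") flag <- "select_fallback"
  xrc <- reconstruct_components(scores)
  list(signal = xrc, s = s, scores = scores, flag = flag,
       hr = estimate_hr_fft(xrc, fps, wcfg$hr_band, wcfg$fft_pad_factor))
}

#' Run the full LA-SSA heart-rate pipeline on a trace
#'
#' Per sliding window: smoothness-prior detrending, normalization,
#' moving-average smoothing, EEMD with in-band mode selection, Hankel
#' embedding and SVD, exact-ALM rank estimation fixing the number of
#' retained components, autocorrelation screening, singular-value-weighted
#' reconstruction, and FFT heart-rate readout.  All randomness (the EEMD
#' ensemble noise) derives from the single `seed`.
#'
#' @param trace a [color_trace()].
#' @param preproc a [preproc_config()].
#' @param embed an [embedding_config()].
#' @param ealm an [ealm_config()].
#' @param select a [select_config()].
#' @param window a [window_config()].
#' @param seed integer seed.
#' @param method "lassa" for the full chain, "eemd" to stop after EEMD
#'   mode selection (spectral readout of the preprocessed series), "raw"
#'   for the readout of the detrended/normalized/smoothed series.
#' @param ablation logical; when TRUE all three readouts are computed in
#'   one pass and returned in `hr_by_method`.
#' @param keep_components logical; retain per-window component score
#'   tables (memory-heavy on long traces).
#' @param verbose logical; one log line per window.
#' @return a `lassa_result`: list with `hr` (an [hr_series()] for
#'   `method`), `signal` (overlap-averaged reconstructed rPPG, full
#'   trace length; NA where no window covers), `hr_by_method` (with
#'   `ablation`), `components` (with `keep_components`), `fps`, `configs`.
#' @export
run_lassa <- function(trace, preproc = preproc_config(),
                      embed = embedding_config(), ealm = ealm_config(),
                      select = select_config(), window = window_config(),
                      seed = 1, method = c("lassa", "eemd", "raw"),
                      ablation = FALSE, keep_components = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(trace, "color_trace"))
  method <- match.arg(method)
  check_scalar(seed, "seed", integerish = TRUE)
  fps <- trace$fps
  n <- length(trace$values)
  starts <- window_starts(n, fps, window)
  win <- round(window$window_seconds * fps)
  need_lassa <- ablation || method == "lassa"
  need_eemd <- ablation || method %in% c("lassa", "eemd")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nw <- length(starts)
  times <- (starts - 1 + (win - 1) / 2) / fps + trace$t0
  hr_raw <- hr_eemd <- hr_lassa <- rep(NA_real_, nw)
  flags <- rep("ok", nw)
  sig_sum <- numeric(n)
  sig_cnt <- numeric(n)
  comps <- if (keep_components) vector("list", nw) else NULL
  pre_raw <- preproc
  pre_raw$use_eemd <- FALSE
  for (j in seq_len(nw)) {
    idx <- starts[j]:(starts[j] + win - 1)
    seg <- trace$values[idx]
    raw <- preprocess_trace(seg, fps, pre_raw)
    hr_raw[j] <- estimate_hr_fft(raw$series, fps, window$hr_band,
                                 window$fft_pad_factor)
    if (need_eemd) {
      pre <- preprocess_trace(seg, fps, preproc)
      hr_eemd[j] <- estimate_hr_fft(pre$series, fps, window$hr_band,
                                    window$fft_pad_factor)
      if (need_lassa) {
        wres <- lassa_window(pre, fps, embed, ealm, select, window)
        hr_lassa[j] <- wres$hr
        flags[j] <- wres$flag
        sig_sum[idx] <- sig_sum[idx] + wres$signal
        sig_cnt[idx] <- sig_cnt[idx] + 1
        if (keep_components) comps[[j]] <- wres$scores$table
      }
    }
    if (verbose) {
      message(sprintf(
        "window %3d/%d @ %6.1f s: hr %s bpm [%s]", j, nw, times[j],
        paste(format(round(stats::na.omit(c(hr_lassa[j], hr_eemd[j],
                                            hr_raw[j])), 1)),
              collapse = "/"),
        flags[j]))
    }
  }
  hr_main <- switch(method, lassa = hr_lassa, eemd = hr_eemd, raw = hr_raw)
  out <- list(hr = hr_series(times, hr_main,
                             if (method == "lassa") flags else "ok"),
              signal = ifelse(sig_cnt > 0, sig_sum / sig_cnt, NA_real_),
              fps = fps,
              configs = list(preproc = preproc, embed = embed, ealm = ealm,
                             select = select, window = window, seed = seed,
                             method = method))
  if (ablation) {
    out$hr_by_method <- list(
      lassa = hr_series(times, hr_lassa, flags),
      eemd = hr_series(times, hr_eemd),
      raw = hr_series(times, hr_raw))
  }
  if (keep_components) out$components <- comps
  structure(out, class = "lassa_result")
}

#' @export
print.lassa_result <- function(x, ...) {
  cat(sprintf("<lassa_result> %d windows, method %s, median HR %.1f bpm\n",
              nrow(x$hr), x$configs$method, stats::median(x$hr$hr_bpm)))
  invisible(x)
}

#' Windowed heart rate of a reference PPG channel
#'
#' Applies the same band-limited spectral-peak readout to a
#' contact-sensor PPG series sampled at `fs`, on the same window grid.
#'
#' @param ppg numeric PPG series.
#' @param fs sampling rate in Hz (> twice the band ceiling).
#' @param window a [window_config()].
#' @param t0 time of the first sample, seconds.
#' @return an [hr_series()].
#' @export
reference_hr_from_ppg <- function(ppg, fs, window = window_config(), t0 = 0) {
  check_series(ppg, "ppg")
  check_scalar(fs, "fs", positive = TRUE)
  stop_if(fs <= 2 * window$hr_band[2],
          "'fs' must exceed twice the pulse-band ceiling")
  starts <- window_starts(length(ppg), fs, window)
  win <- round(window$window_seconds * fs)
  hr <- vapply(starts, function(s0) {
    estimate_hr_fft(ppg[s0:(s0 + win - 1)], fs, window$hr_band,
                    window$fft_pad_factor)
  }, numeric(1))
  hr_series((starts - 1 + (win - 1) / 2) / fs + t0, hr)
}

#' Agreement metrics between estimated and reference heart rate
#'
#' Matches windows by nearest center (within half the median reference
#' step) and reports MAE, RMSE, Pearson correlation, and the Bland-Altman
#' mean difference with 95% limits of agreement
#' `mean_diff -/+ 1.96 sd(diff)`.
#'
#' @param est estimated [hr_series()].
#' @param ref reference [hr_series()].
#' @return an `eval_report`: list with `mae_bpm`, `rmse_bpm`, `pearson_r`,
#'   `bland_altman` (`mean_diff`, `loa_low`, `loa_high`), `n_windows`.
#' @export
evaluate_hr <- function(est, ref) {
  stop_if(!inherits(est, "hr_series") || !inherits(ref, "hr_series"),
          "'est' and 'ref' must be hr_series objects")
  step <- if (nrow(ref) > 1) stats::median(diff(ref$time)) else Inf
  nearest <- vapply(est$time, function(t) {
    i <- which.min(abs(ref$time - t))
    if (abs(ref$time[i] - t) <= step / 2 + 1e-9) i else NA_integer_
  }, integer(1))
  ok <- !is.na(nearest) & is.finite(est$hr_bpm)
  stop_if(sum(ok) < 2, "fewer than 2 common windows to compare")
  e <- est$hr_bpm[ok]
  r <- ref$hr_bpm[nearest[ok]]
  d <- e - r
  sdd <- stats::sd(d)
  structure(list(mae_bpm = mean(abs(d)),
                 rmse_bpm = sqrt(mean(d^2)),
                 pearson_r = if (stats::sd(e) == 0 || stats::sd(r) == 0)
                   NA_real_ else stats::cor(e, r),
                 bland_altman = list(mean_diff = mean(d),
                                     loa_low = mean(d) - 1.96 * sdd,
                                     loa_high = mean(d) + 1.96 * sdd),
                 n_windows = sum(ok)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report> n=%d windows\n  MAE  %.2f bpm\n  RMSE %.2f bpm\n",
           "  r    %.3f\n  Bland-Altman %.2f [%.2f, %.2f] bpm\n"),
    x$n_windows, x$mae_bpm, x$rmse_bpm, x$pearson_r,
    x$bland_altman$mean_diff, x$bland_altman$loa_low,
    x$bland_altman$loa_high))
  invisible(x)
}

#' Ground-truth windowed heart rate of a simulated trace
#'
#' Averages the generator's instantaneous heart-rate schedule over the
#' same window grid the pipeline uses, giving the reference an estimate
#' should be compared against.
#'
#' @param sim a [simulate_pulse_trace()] result.
#' @param window a [window_config()].
#' @return an [hr_series()].
#' @export
true_hr_windows <- function(sim, window = window_config()) {
  stopifnot(inherits(sim, "pulse_sim"))
  fps <- sim$trace$fps
  starts <- window_starts(length(sim$hr_bpm), fps, window)
  win <- round(window$window_seconds * fps)
  hr <- vapply(starts, function(s0) mean(sim$hr_bpm[s0:(s0 + win - 1)]),
               numeric(1))
  hr_series((starts - 1 + (win - 1) / 2) / fps + sim$trace$t0, hr)
}
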