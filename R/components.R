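#' Component-screening configuration
#'
#' Parameters of the local periodicity screen applied to each retained
#' trajectory component: the autocorrelation is computed out to
#' `max_lag_seconds` and a component is kept when its maximum interior
#' autocorrelation peak exceeds `rho_threshold`.
#'
#' @param rho_threshold selection threshold on the maximum autocorrelation
#'   coefficient, in (0, 1); default 0.85.
#' @param max_lag_seconds autocorrelation horizon in seconds (12 s covers
#'   the longest cardiovascular fluctuation period).
#' @param peak_min_separation_s minimum spacing between counted peaks, in
#'   seconds; suppresses jitter peaks.  Converted to lags with the
#'   sampling rate at use.
#' @param weight_denominator "selected" normalizes reconstruction weights
#'   over the selected set (weights sum to 1); "all" divides by the total
#'   of all retained singular values.
#' @return a `select_config` list.
#' @export
select_config <- function(rho_threshold = 0.85, max_lag_seconds = 12,
                          peak_min_separation_s = 0.25,
                          weight_denominator = c("selected", "all")) {
  check_scalar(rho_threshold, "rho_threshold")
  stop_if(rho_threshold <= 0 || rho_threshold >= 1,
          "'rho_threshold' must lie in (0, 1)")
  check_scalar(max_lag_seconds, "max_lag_seconds", positive = TRUE)
  check_scalar(peak_min_separation_s, "peak_min_separation_s")
  stop_if(peak_min_separation_s < 0,
          "'peak_min_separation_s' must be >= 0")
  weight_denominator <- match.arg(weight_denominator)
  structure(list(rho_threshold = rho_threshold,
                 max_lag_seconds = max_lag_seconds,
                 peak_min_separation_s = peak_min_separation_s,
                 weight_denominator = weight_denominator),
            class = "select_config")
}

#' Normalized sample autocorrelation
#'
#' The biased normalized estimator
#' `P(k) = sum_t (z_t - mu)(z_{t+k} - mu) / (N sigma^2)` with `mu` and
#' `sigma^2` the sample mean and (divisor-N) variance of `z`, so that
#' `P(0) = 1` exactly and `|P(k)| <= 1`.
#'
#' @param z numeric series with nonzero variance.
#' @param max_lag largest lag (must be < length(z)).
#' @return numeric vector `P(0), ..., P(max_lag)`.
#' @export
autocorrelation <- function(z, max_lag) {
  check_series(z, "z")
  check_scalar(max_lag, "max_lag", integerish = TRUE)
  stop_if(max_lag < 0 || max_lag >= length(z),
          "'max_lag' must be in [0, length(z) - 1]")
  stop_if(stats::var(z) == 0, "'z' has zero variance")
  as.numeric(.autocorr_c(z, as.integer(max_lag)))
}

# Strict local maxima of P at lag >= 1 (plateaus keep their left edge),
# thinned so surviving peaks are at least min_sep lags apart (higher peak
# wins) and at least min_sep lags away from lag 0.
find_acf_peaks <- function(P, min_sep = 1L) {
  n <- length(P)
  if (n < 3) return(integer(0))
  k <- which(diff(sign(diff(P))) < 0) + 1  # index into P, 1-based
  k <- k[k > 1]                            # interior lags only (lag >= 1)
  k <- k[(k - 1) >= min_sep]               # keep clear of the lag-0 maximum
  if (length(k) < 2 || min_sep <= 1) return(k)
  ord <- order(P[k], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(k[i] - kept) >= min_sep)) kept <- c(kept, k[i])
  }
  sort(kept)
}

#' Maximum autocorrelation coefficient of a component
#'
#' Scans the interior peaks of the autocorrelation (the lag-0 maximum
#' counts as the first peak, so scoring starts from the first peak at
#' positive lag) and returns the largest peak value.  A series whose
#' autocorrelation has no interior peak scores the sentinel -1, which can
#' never pass a selection threshold.
#'
#' @param P autocorrelation series from [autocorrelation()].
#' @param cfg a [select_config()].
#' @param fps sampling rate; converts `peak_min_separation_s` to lags
#'   (separation 1 lag when omitted).
#' @return scalar `rho` in [-1, 1].
#' @export
max_autocorr_coefficient <- function(P, cfg = select_config(), fps = NULL) {
  check_series(P, "P")
  min_sep <- if (is.null(fps)) 1L else
    max(1L, as.integer(round(cfg$peak_min_separation_s * fps)))
  pk <- find_acf_peaks(P, min_sep)
  if (length(pk) == 0) -1 else max(P[pk])
}

#' Score and select periodic trajectory components
#'
#' For the first `s` components of an SSA decomposition, forms each
#' component series by diagonal averaging, scores its maximum
#' autocorrelation coefficient, and flags components above the threshold.
#' When no component passes, the single highest-scoring component is kept
#' as a fallback (flagged) so reconstruction is never empty.
#'
#' @param decomp an [ssa_decompose()] result.
#' @param s number of leading components retained globally
#'   (1 <= s <= d).
#' @param cfg a [select_config()].
#' @param fps sampling rate in frames/second.
#' @return a `component_scores` list: `table` (data.frame with index,
#'   lambda, rho, selected, weight), `series` (N x s matrix of component
#'   series), `fallback` (TRUE when the empty-selection fallback fired).
#' @export
select_components <- function(decomp, s, cfg = select_config(), fps) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  check_scalar(s, "s", integerish = TRUE)
  stop_if(s < 1, "'s' must be >= 1")
  s <- min(s, decomp$d)
  check_scalar(fps, "fps", positive = TRUE)
  max_lag <- min(as.integer(round(cfg$max_lag_seconds * fps)), decomp$N - 1)
  # anti-diagonal averages of the rank-1 component matrices, computed as
  # scaled convolutions of the singular-vector pairs
  z <- .component_series_c(decomp$u[, seq_len(s), drop = FALSE],
                           decomp$v[, seq_len(s), drop = FALSE],
                           decomp$values[seq_len(s)])
  rho <- vapply(seq_len(s), function(i) {
    zi <- z[, i]
    if (stats::var(zi) == 0) return(-1)
    max_autocorr_coefficient(autocorrelation(zi, max_lag), cfg, fps)
  }, numeric(1))
  selected <- rho > cfg$rho_threshold
  fallback <- FALSE
  if (!any(selected)) {
    selected[which.max(rho)] <- TRUE
    fallback <- TRUE
  }
  lambda <- decomp$values[seq_len(s)]
  denom <- if (cfg$weight_denominator == "selected")
    sum(lambda[selected]) else sum(lambda)
  w <- ifelse(selected, lambda / denom, 0)
  structure(list(table = data.frame(index = seq_len(s), lambda = lambda,
                                    rho = rho, selected = selected,
                                    weight = w),
                 series = z, fallback = fallback),
            class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("<component_scores> %d scored, %d selected%s\n",
              nrow(x$table), sum(x$table$selected),
              if (x$fallback) " (fallback)" else ""))
  print(x$table, ...)
  invisible(x)
}

#' Weighted reconstruction of the denoised signal
#'
#' Superposes the selected component series with weights proportional to
#' their singular values: `x_rc = sum_{i in S} w_i z_i`.
#'
#' @param scores a [select_components()] result.
#' @return numeric series of length N.
#' @export
reconstruct_components <- function(scores) {
  stopifnot(inherits(scores, "component_scores"))
  sel <- scores$table$selected
  stop_if(!any(sel), "no selected components")
  as.numeric(scores$series[, sel, drop = FALSE] %*%
               scores$table$weight[sel])
}

#' Write a per-component debug table to CSV
#'
#' @param scores a [select_components()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_component_csv <- function(scores, path) {
  stopifnot(inherits(scores, "component_scores"))
  utils::write.csv(scores$table, path, row.names = FALSE)
  invisible(path)
}
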