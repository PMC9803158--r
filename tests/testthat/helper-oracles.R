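# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities from first principles (double loops, dense solves,
# base-R transforms) so they share no code with the implementation paths
# they check.

# Literal double-loop evaluation of the biased normalized autocorrelation.
acf_bruteforce <- function(z, max_lag) {
  n <- length(z)
  mu <- mean(z)
  sigma2 <- sum((z - mu)^2) / n
  p <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    for (t in 1:(n - k)) s <- s + (z[t] - mu) * (z[t + k] - mu)
    p[k + 1] <- s / (n * sigma2)
  }
  p
}

# Anti-diagonal means by explicit double loop.
diag_avg_bruteforce <- function(Xi) {
  L <- nrow(Xi); K <- ncol(Xi); n <- L + K - 1
  out <- numeric(n)
  for (k in 1:n) {
    vals <- c()
    for (i in 1:L) {
      j <- k - i + 1
      if (j >= 1 && j <= K) vals <- c(vals, Xi[i, j])
    }
    out[k] <- mean(vals)
  }
  out
}

# Dense direct solve of the smoothness-prior trend (small n only).
detrend_bruteforce <- function(x, lambda) {
  n <- length(x)
  D <- matrix(0, n - 2, n)
  for (i in 1:(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  x - as.numeric(solve(diag(n) + lambda^2 * crossprod(D), x))
}

# Per-pixel skin predicate evaluated literally, hue via base R's rgb2hsv.
skin_pixel_bruteforce <- function(r, g, b, rule = lassa::skin_rule()) {
  h <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)[1, ] * 360
  r > rule$r_min & g > rule$g_min & b > rule$b_min &
    (pmax(r, g, b) - pmin(r, g, b)) > rule$chroma_spread_min &
    r > g & r > b & h >= rule$h_min & h <= rule$h_max
}

# Dominant FFT frequency of a series (periodogram argmax).
dominant_freq <- function(x, fps) {
  n <- length(x)
  nfft <- 2^ceiling(log2(8 * n))
  mag <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))
  half <- 2:(nfft %/% 2)
  (half[which.max(mag[half])] - 1) * fps / nfft
}

# Band power from the raw periodogram.
band_power <- function(x, fps, f_lo, f_hi) {
  n <- length(x)
  mag2 <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fps / n
  sum(mag2[f >= f_lo & f <= f_hi])
}
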