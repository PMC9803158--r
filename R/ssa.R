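#' Embedding window configuration
#'
#' The trajectory window is specified in seconds and converted to
#' `L = round(window_seconds * fps)` samples.  The 3 s default is a
#' quarter of the longest cardiovascular fluctuation period (about 12 s),
#' the usual sizing rule for periodic series.
#'
#' @param window_seconds embedding window length in seconds.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(window_seconds = 3) {
  check_scalar(window_seconds, "window_seconds", positive = TRUE)
  structure(list(window_seconds = window_seconds), class = "embedding_config")
}

#' Build the Hankel trajectory matrix
#'
#' Row `i` of the `L x K` result is the series delayed by `i - 1` samples,
#' `K = N - L + 1`; anti-diagonals are constant.
#'
#' @param x numeric series of length N.
#' @param L window length in samples, `1 < L < N`.
#' @return an `L x K` matrix.
#' @export
build_trajectory <- function(x, L) {
  check_series(x, "x", min_len = 3L)
  check_scalar(L, "L", positive = TRUE, integerish = TRUE)
  n <- length(x)
  stop_if(L <= 1 || L >= n, "'L' must satisfy 1 < L < length(x)")
  K <- n - L + 1
  matrix(x[rep(seq_len(L), K) + rep(0:(K - 1), each = L)], L, K)
}

#' Singular value decomposition of a trajectory matrix
#'
#' Wraps the SVD and drops singular values at numerical zero
#' (below `max(sv) * max(dim) * machine epsilon`), so `d` counts only
#' genuine components.
#'
#' @param X numeric matrix (finite entries).
#' @return an `ssa_decomposition`: list with `values` (singular values,
#'   nonincreasing), `u` (L x d), `v` (K x d), `d`, `L`, `K`, `N`.
#' @export
ssa_decompose <- function(X) {
  stop_if(!is.matrix(X) || !is.numeric(X) || any(!is.finite(X)),
          "'X' must be a finite numeric matrix")
  sv <- svd(X)
  tol <- if (sv$d[1] > 0) sv$d[1] * max(dim(X)) * .Machine$double.eps else 0
  d <- sum(sv$d > tol)
  d <- max(d, 0L)
  keep <- seq_len(d)
  structure(list(values = sv$d[keep], u = sv$u[, keep, drop = FALSE],
                 v = sv$v[, keep, drop = FALSE], d = d,
                 L = nrow(X), K = ncol(X), N = nrow(X) + ncol(X) - 1),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf("<ssa_decomposition> L=%d, K=%d, d=%d nonzero singular values\n",
              x$L, x$K, x$d))
  invisible(x)
}

#' Diagonal averaging (hankelization)
#'
#' Maps an `L x K` matrix back to a series of length `N = L + K - 1` by
#' averaging each anti-diagonal; the exact inverse of [build_trajectory()]
#' on Hankel matrices.
#'
#' @param Xi numeric matrix.
#' @return numeric series of length `nrow(Xi) + ncol(Xi) - 1`.
#' @export
diagonal_average <- function(Xi) {
  stop_if(!is.matrix(Xi) || !is.numeric(Xi), "'Xi' must be a numeric matrix")
  L <- nrow(Xi); K <- ncol(Xi); n <- L + K - 1
  s <- numeric(n)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1)
    s[idx] <- s[idx] + Xi[i, ]
  }
  s / pmin(seq_len(n), min(L, K), n - seq_len(n) + 1)
}

# Series of the i-th elementary component lambda_i u_i v_i^T.
component_series <- function(decomp, i) {
  diagonal_average(decomp$values[i] *
                     tcrossprod(decomp$u[, i], decomp$v[, i]))
}

#' Dump the singular spectrum to CSV
#'
#' Writes one row per component: index, singular value, and its
#' proportion of the spectrum total — the numbers behind
#' singular-value-ratio plots.
#'
#' @param decomp an [ssa_decompose()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_singular_spectrum_csv <- function(decomp, path) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  utils::write.csv(data.frame(index = seq_len(decomp$d),
                              value = decomp$values,
                              proportion = decomp$values /
                                sum(decomp$values)),
                   path, row.names = FALSE)
  invisible(path)
}
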