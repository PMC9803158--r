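#' Exact ALM robust-PCA configuration
#'
#' Controls the augmented-Lagrange-multiplier solver for the split
#' `X = A + E` (nuclear-norm low-rank part plus l1 sparse part).  The
#' sparsity weight defaults to the literature-standard
#' `eta = 1/sqrt(max(m, n))`, under which exact recovery of a low-rank
#' matrix from sparse corruption holds; `eta_mode = "dims"` switches to
#' `1/max(m, n)`, a much weaker sparsity penalty that drives nearly all
#' energy into the sparse part (see the methods vignette).
#'
#' @param eta explicit sparsity weight; overrides `eta_mode` when given.
#' @param eta_mode "sqrt" for `1/sqrt(max(m, n))` (default) or "dims" for
#'   `1/max(m, n)`.
#' @param mu0 initial penalty; default `1.25 / ||X||_2` chosen at run time.
#' @param rho_growth penalty growth factor per outer iteration, in
#'   [1.1, 2].
#' @param tol relative Frobenius residual `||X - A - E||_F / ||X||_F`
#'   declaring convergence.
#' @param max_outer outer iteration cap.
#' @param inner_tol relative change threshold ending the inner A/E
#'   alternation (relative to the norms of the current iterates).
#' @param max_inner inner alternation cap per outer iteration.  The
#'   alternation contracts quickly once the penalty is large, so a loose
#'   inner stop loses no recovery accuracy (see the methods vignette).
#' @return an `ealm_config` list.
#' @export
ealm_config <- function(eta = NULL, eta_mode = c("sqrt", "dims"), mu0 = NULL,
                        rho_growth = 1.5, tol = 1e-7, max_outer = 500,
                        inner_tol = 1e-4, max_inner = 10) {
  eta_mode <- match.arg(eta_mode)
  if (!is.null(eta)) check_scalar(eta, "eta", positive = TRUE)
  if (!is.null(mu0)) check_scalar(mu0, "mu0", positive = TRUE)
  check_scalar(rho_growth, "rho_growth", positive = TRUE)
  stop_if(rho_growth < 1.1 || rho_growth > 2,
          "'rho_growth' must lie in [1.1, 2]")
  check_scalar(tol, "tol", positive = TRUE)
  check_scalar(max_outer, "max_outer", positive = TRUE, integerish = TRUE)
  check_scalar(inner_tol, "inner_tol", positive = TRUE)
  check_scalar(max_inner, "max_inner", positive = TRUE, integerish = TRUE)
  structure(as.list(environment()), class = "ealm_config")
}

#' Soft (shrinkage) threshold
#'
#' `sign(x) * max(|x| - tau, 0)` elementwise: the proximal operator of the
#' l1 norm.
#'
#' @param x numeric scalar, vector, or matrix.
#' @param tau threshold, >= 0.
#' @return object of the same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  check_scalar(tau, "tau")
  stop_if(tau < 0, "'tau' must be >= 0")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Singular value soft threshold
#'
#' SVD of `M` with soft-thresholded singular values, recomposed: the
#' proximal operator of the nuclear norm.
#'
#' @param M numeric matrix.
#' @param tau threshold, >= 0.
#' @return matrix of the same dimensions as `M`.
#' @export
sv_threshold <- function(M, tau) {
  stop_if(!is.matrix(M) || !is.numeric(M), "'M' must be a numeric matrix")
  check_scalar(tau, "tau")
  stop_if(tau < 0, "'tau' must be >= 0")
  sv <- svd(M)
  dt <- pmax(sv$d - tau, 0)
  keep <- dt > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (dt[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Initial Lagrange multiplier
#'
#' `Y0 = sign(X) / max(||sign(X)||_2, eta^{-1} ||sign(X)||_inf)`, with the
#' spectral norm and the maximum absolute entry (1 for any nonzero X).
#'
#' @param X nonzero numeric matrix.
#' @param eta sparsity weight of the robust-PCA objective.
#' @return matrix of the same dimensions as `X`.
#' @export
initial_multiplier <- function(X, eta) {
  stop_if(!is.matrix(X) || !is.numeric(X), "'X' must be a numeric matrix")
  check_scalar(eta, "eta", positive = TRUE)
  s <- sign(X)
  stop_if(all(s == 0), "'X' must be nonzero")
  s / max(norm(s, type = "2"), max(abs(s)) / eta)
}

resolve_eta <- function(cfg, m, n) {
  if (!is.null(cfg$eta)) return(cfg$eta)
  if (cfg$eta_mode == "sqrt") 1 / sqrt(max(m, n)) else 1 / max(m, n)
}

#' Low-rank + sparse split by the exact ALM method
#'
#' Alternates the singular-value shrinkage update of the low-rank part A
#' and the elementwise shrinkage update of the sparse part E to inner
#' convergence at fixed multiplier Y and penalty mu, then takes the
#' multiplier ascent step `Y <- Y + mu (X - A - E)` and grows mu, until
#' the relative residual meets `tol`.  The estimated rank `s` of A (the
#' number of trajectory components retained downstream) is the count of
#' singular values above `max(sv) * max(dim) * eps * 10`, clamped to at
#' least 1 for nonzero input.
#'
#' @param X finite, nonzero numeric matrix.
#' @param cfg an [ealm_config()].
#' @param diagnostics logical; record the augmented Lagrangian value at
#'   every inner iteration (for convergence inspection).
#' @param verbose logical; per-outer-iteration residual/rank log line.
#' @return a `lowrank_split`: list with `A`, `E`, `s`, `iterations`,
#'   `final_residual`, `converged`, `eta`, and (with `diagnostics`)
#'   `residual_trace`, `lagrangian`, `lagrangian_outer`.
#' @export
ealm_decompose <- function(X, cfg = ealm_config(), diagnostics = FALSE,
                           verbose = FALSE) {
  stop_if(!is.matrix(X) || !is.numeric(X) || any(!is.finite(X)),
          "'X' must be a finite numeric matrix")
  stop_if(all(X == 0), "'X' must be nonzero")
  stopifnot(inherits(cfg, "ealm_config"))
  eta <- resolve_eta(cfg, nrow(X), ncol(X))
  mu0 <- if (is.null(cfg$mu0)) 1.25 / norm(X, type = "2") else cfg$mu0
  Y0 <- initial_multiplier(X, eta)
  res <- .ealm_c(X, Y0, eta, mu0, cfg$rho_growth, cfg$tol, cfg$max_outer,
                 cfg$inner_tol, cfg$max_inner, diagnostics)
  if (verbose) {
    tr <- res$residual_trace
    for (i in seq_along(tr))
      message(sprintf("ealm outer %3d: residual %.3e", i, tr[i]))
  }
  out <- list(A = res$A, E = res$E, s = max(res$s, 1L),
              iterations = res$iterations,
              final_residual = res$final_residual,
              converged = res$converged, eta = eta)
  if (diagnostics) {
    out$residual_trace <- res$residual_trace
    out$lagrangian <- res$lagrangian
    out$lagrangian_outer <- res$lagrangian_outer
  }
  structure(out, class = "lowrank_split")
}

#' @export
print.lowrank_split <- function(x, ...) {
  cat(sprintf(
    "<lowrank_split> rank s=%d, %d outer iterations, residual %.2e (%s)\n",
    x$s, x$iterations, x$final_residual,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
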