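# Adaptive iteratively reweighted penalized least squares (airPLS) baseline
# estimation, built on sparse Whittaker solves.

#' Weighted Whittaker smoother (single solve)
#'
#' Solves argmin_z sum_i w_i (x_i - z_i)^2 + lambda * sum (d2 z)^2 using the
#' sparse banded system (W + lambda D'D) z = W x, with D the second-difference
#' operator. Internal; exposed for the dense-matrix agreement tests.
#' @noRd
whittaker_solve <- function(x, w, lambda, DtD = NULL) {
  P <- length(x)
  if (is.null(DtD)) DtD <- second_diff_penalty(P)
  A <- Matrix::Diagonal(x = w) + lambda * DtD
  as.numeric(Matrix::solve(A, w * x))
}

#' Sparse D'D for the second-difference penalty on P points
#' @noRd
second_diff_penalty <- function(P) {
  D <- Matrix::bandSparse(P - 2L, P, k = 0:2,
                          diagonals = list(rep(1, P - 2L),
                                           rep(-2, P - 2L),
                                           rep(1, P - 2L)))
  Matrix::crossprod(D)
}

#' airPLS baseline correction
#'
#' Fits the smooth fluorescence background of each spectrum by adaptive
#' iteratively reweighted penalized least squares. Each iteration solves the
#' weighted Whittaker problem, then re-weights: points at or above the
#' current baseline (candidate Raman peaks) get weight 0, points below get
#' weight `exp(t * |x_i - z_i| / |d|_1)` where `d` collects the negative
#' residuals and `t` is the iteration index, so the baseline is pulled
#' towards the lower envelope of the signal. Iteration stops when
#' `|d|_1 < tol * |x|_1` or at `max_iter` (with a warning).
#'
#' @param x A [SpectrumSet-class] (or a single numeric spectrum).
#' @param lambda Smoothness weight (> 0); larger values give stiffer
#'   baselines. Default `1e5`, appropriate for ~1 cm^-1 point spacing.
#' @param max_iter Maximum iterations (default 30).
#' @param tol Convergence ratio in (0, 1), default `1e-3`.
#' @return A list of class `"baselineResult"` with elements `baseline` and
#'   `corrected` (each shaped like the input intensities; `corrected` is
#'   exactly `input - baseline`), `iterations_used` (per spectrum), and
#'   `set` — the input `SpectrumSet` with corrected intensities (when the
#'   input was a `SpectrumSet`).
#' @examples
#' wn <- seq(500, 700, by = 2)
#' spec <- 0.002 * wn + exp(-(wn - 600)^2 / 50)
#' res <- baselineAirPLS(SpectrumSet(wn, cbind(s = spec)))
#' max(abs(res$corrected + res$baseline - spec)) < 1e-12
#' @export
baselineAirPLS <- function(x, lambda = 1e5, max_iter = 30L, tol = 1e-3) {
  stopifnot(lambda > 0, max_iter >= 1, tol > 0, tol < 1)
  is_set <- methods::is(x, "SpectrumSet")
  mat <- if (is_set) intensities(x) else cbind(as.numeric(x))
  P <- nrow(mat)
  if (P < 3) stop("airPLS needs at least 3 points")
  DtD <- second_diff_penalty(P)
  baseline <- mat
  iters <- integer(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    xi <- mat[, s]
    w <- rep(1, P)
    absx <- sum(abs(xi))
    z <- xi
    for (t in seq_len(max_iter)) {
      z <- whittaker_solve(xi, w, lambda, DtD)
      d <- xi - z
      neg <- d < 0
      dssn <- sum(abs(d[neg]))
      iters[s] <- t
      if (dssn < tol * absx) break
      if (t == max_iter) {
        warning(sprintf("airPLS did not converge for spectrum %d (|d|1/|x|1 = %.3g)",
                        s, dssn / absx))
        break
      }
      w[!neg] <- 0
      w[neg] <- exp(t * abs(d[neg]) / dssn)
    }
    baseline[, s] <- z
  }
  corrected <- mat - baseline
  out <- list(baseline = baseline, corrected = corrected,
              iterations_used = iters)
  if (is_set) out$set <- set_intensities(x, corrected)
  structure(out, class = "baselineResult")
}
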