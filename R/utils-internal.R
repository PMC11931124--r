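# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' operations never perturb the surrounding random stream. `seed = NULL`
#' leaves the current stream untouched (and advances it).
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Numerically stable log(1 + exp(x))
#' @noRd
softplus <- function(x) {
  out <- x
  lo <- x < 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

#' Logistic sigmoid (the softplus derivative)
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Trapezoidal integral of y over (possibly non-uniform) x
#' @noRd
trapz_integral <- function(x, y) pracma::trapz(x, y)

#' Shannon entropy (nats) of a probability vector; 0 * log 0 := 0
#' @noRd
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
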