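# Variational (Bayes-by-backprop) layer primitives: Gaussian weight
# posteriors with a softplus scale parameterization, reparameterized
# sampling, closed-form KL to an isotropic Gaussian prior, and the
# Bayesian 1-D convolution / linear forward operations.

#' Prior/posterior parameterization of a variational layer
#'
#' Every weight (and bias) of a Bayesian layer carries an independent
#' Gaussian posterior `N(mu, sigma^2)` with `sigma = softplus(rho)`, trained
#' against an isotropic Gaussian prior `N(prior_mu, prior_sigma^2)`.
#' Initialization draws `mu ~ N(post_mu_init_mean, post_mu_init_sd)` and
#' `rho ~ N(post_rho_init_mean, post_rho_init_sd)`. The default
#' `post_rho_init_mean = -3` gives an initial weight sd of
#' `softplus(-3) ~ 0.0486`, well inside the prior scale 0.1 — the usual
#' Bayes-by-backprop convention where the log-scale init is a small negative
#' number. A positive value (initial sd ~ 3, far wider than the prior)
#' remains selectable.
#'
#' @param prior_mu,prior_sigma Prior location and scale (`prior_sigma > 0`);
#'   defaults 0 and 0.1.
#' @param post_mu_init_mean,post_mu_init_sd Posterior-mean init distribution;
#'   defaults 0 and 0.1.
#' @param post_rho_init_mean,post_rho_init_sd Pre-softplus scale init
#'   distribution; defaults -3 and 0.1.
#' @return A list of class `"variationalLayerSpec"`.
#' @export
variationalLayerSpec <- function(prior_mu = 0, prior_sigma = 0.1,
                                 post_mu_init_mean = 0, post_mu_init_sd = 0.1,
                                 post_rho_init_mean = -3,
                                 post_rho_init_sd = 0.1) {
  stopifnot(prior_sigma > 0, post_mu_init_sd >= 0, post_rho_init_sd >= 0)
  structure(list(prior_mu = prior_mu, prior_sigma = prior_sigma,
                 post_mu_init_mean = post_mu_init_mean,
                 post_mu_init_sd = post_mu_init_sd,
                 post_rho_init_mean = post_rho_init_mean,
                 post_rho_init_sd = post_rho_init_sd),
            class = "variationalLayerSpec")
}

#' Initialize a variational posterior for a weight tensor
#'
#' @param spec A [variationalLayerSpec()].
#' @param shape Integer vector, the weight tensor shape (nonempty).
#' @param seed Optional RNG seed.
#' @return A list of class `"variationalPosterior"` with arrays `mu` and
#'   `rho` of dimension `shape`.
#' @examples
#' p <- initPosterior(variationalLayerSpec(), c(4, 3), seed = 1)
#' range(posteriorSigma(p))
#' @export
initPosterior <- function(spec, shape, seed = NULL) {
  stopifnot(inherits(spec, "variationalLayerSpec"))
  shape <- as.integer(shape)
  if (!length(shape) || any(shape < 1)) stop("shape must be a nonempty positive vector")
  n <- prod(shape)
  with_seed(seed, {
    mu <- array(stats::rnorm(n, spec$post_mu_init_mean, spec$post_mu_init_sd),
                dim = shape)
    rho <- array(stats::rnorm(n, spec$post_rho_init_mean, spec$post_rho_init_sd),
                 dim = shape)
    structure(list(mu = mu, rho = rho), class = "variationalPosterior")
  })
}

#' @rdname initPosterior
#' @param post A `"variationalPosterior"`.
#' @export
posteriorSigma <- function(post) softplus(post$rho)

#' Draw weights by the reparameterization trick
#'
#' Returns `w = mu + softplus(rho) * eps`. Given the same `eps` (or the same
#' seed) the draw is deterministic.
#'
#' @param post A `"variationalPosterior"`.
#' @param eps Standard-normal noise tensor matching the weight shape, or
#'   `NULL` to draw one from the current RNG stream.
#' @param seed Optional seed for the internal draw.
#' @return A weight array shaped like `post$mu`.
#' @export
sampleWeights <- function(post, eps = NULL, seed = NULL) {
  stopifnot(inherits(post, "variationalPosterior"))
  if (is.null(eps)) {
    eps <- with_seed(seed, array(stats::rnorm(length(post$mu)), dim = dim(post$mu)))
  } else {
    if (length(eps) != length(post$mu)) {
      stop("eps shape does not match the weight tensor")
    }
    eps <- array(as.numeric(eps), dim = dim(post$mu))
  }
  post$mu + posteriorSigma(post) * eps
}

#' Closed-form KL divergence from posterior to prior
#'
#' Sum over weights of
#' `log(sigma0/sigma) + (sigma^2 + (mu - mu0)^2) / (2 sigma0^2) - 1/2`,
#' the KL divergence between independent Gaussians. Zero iff the posterior
#' equals the prior, nonnegative always.
#'
#' @param post A `"variationalPosterior"`.
#' @param spec The [variationalLayerSpec()] carrying the prior.
#' @return Nonnegative scalar.
#' @export
klToPrior <- function(post, spec) {
  stopifnot(inherits(post, "variationalPosterior"),
            inherits(spec, "variationalLayerSpec"))
  sigma <- posteriorSigma(post)
  kl_gaussians(post$mu, sigma, spec$prior_mu, spec$prior_sigma)
}

#' Elementwise Gaussian KL, summed
#' @noRd
kl_gaussians <- function(mu, sigma, mu0, sigma0) {
  sum(log(sigma0 / sigma) + (sigma^2 + (mu - mu0)^2) / (2 * sigma0^2) - 0.5)
}

#' Bayesian 1-D convolution (single forward evaluation)
#'
#' Ordinary 1-D cross-correlation whose kernel (and bias) are either a
#' reparameterized posterior draw (`sample = TRUE`) or the posterior means
#' (`sample = FALSE`, the deterministic "posterior-mean" mode).
#'
#' @param input Numeric array `batch x in_channels x length`.
#' @param kernel_post A `"variationalPosterior"` with shape
#'   `(out_channels, in_channels, kernel_size)`.
#' @param bias_post Optional `"variationalPosterior"` of shape
#'   `(out_channels)`; `NULL` for no bias.
#' @param stride,padding Convolution geometry (defaults 1 and 0; zero
#'   padding).
#' @param sample Draw weights stochastically (default `TRUE`).
#' @param seed Seed for the draw.
#' @return Array `batch x out_channels x out_length`.
#' @export
bayesConv1d <- function(input, kernel_post, bias_post = NULL, stride = 1L,
                        padding = 0L, sample = TRUE, seed = NULL) {
  stopifnot(length(dim(input)) == 3,
            inherits(kernel_post, "variationalPosterior"))
  kd <- dim(kernel_post$mu)
  if (length(kd) != 3) stop("kernel posterior must be (out, in, k)")
  if (dim(input)[2] != kd[2]) {
    stop(sprintf("input has %d channels but kernel expects %d",
                 dim(input)[2], kd[2]))
  }
  with_seed(seed, {
    W <- if (sample) sampleWeights(kernel_post) else kernel_post$mu
    b <- if (is.null(bias_post)) rep(0, kd[1])
         else if (sample) as.numeric(sampleWeights(bias_post))
         else as.numeric(bias_post$mu)
    x <- aperm(input, c(2, 3, 1))                   # (C, L, B)
    Wm <- matrix(W, nrow = kd[1])                   # (out, in*k), in fastest
    out <- conv1d_forward(x, Wm, b, kd[3], stride, padding)$out
    aperm(out, c(3, 1, 2))                          # (B, out, Lo)
  })
}

#' Bayesian linear layer (single forward evaluation)
#'
#' @param input Numeric matrix `batch x in_features`.
#' @param weight_post A `"variationalPosterior"` of shape
#'   `(out_features, in_features)`.
#' @param bias_post Optional posterior of shape `(out_features)`.
#' @param sample,seed As in [bayesConv1d()].
#' @return Matrix `batch x out_features`.
#' @export
bayesLinear <- function(input, weight_post, bias_post = NULL, sample = TRUE,
                        seed = NULL) {
  input <- as.matrix(input)
  stopifnot(inherits(weight_post, "variationalPosterior"))
  wd <- dim(weight_post$mu)
  if (length(wd) != 2) stop("weight posterior must be (out, in)")
  if (ncol(input) != wd[2]) {
    stop(sprintf("input has %d features but weights expect %d",
                 ncol(input), wd[2]))
  }
  with_seed(seed, {
    W <- if (sample) sampleWeights(weight_post) else weight_post$mu
    b <- if (is.null(bias_post)) rep(0, wd[1])
         else if (sample) as.numeric(sampleWeights(bias_post))
         else as.numeric(bias_post$mu)
    t(W %*% t(input) + b)
  })
}
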