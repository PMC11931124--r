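test_that("posterior initialization follows its spec", {
  # degenerate init: sd 0 pins mu exactly
  sp0 <- variationalLayerSpec(post_mu_init_sd = 0, post_rho_init_sd = 0)
  p0 <- initPosterior(sp0, c(3, 4), seed = 1)
  expect_true(all(p0$mu == 0))
  # rho mean -3 gives initial weight sd softplus(-3) = log(1 + e^-3)
  expect_equal(unique(as.numeric(posteriorSigma(p0))), log(1 + exp(-3)),
               tolerance = 1e-12)
  expect_equal(log(1 + exp(-3)), 0.04858735, tolerance = 1e-7)

  # Monte-Carlo: the mu sample mean matches its init mean within 3 SE
  sp <- variationalLayerSpec()
  p <- initPosterior(sp, c(1000, 1000), seed = 2)
  se <- sp$post_mu_init_sd / sqrt(length(p$mu))
  expect_lt(abs(mean(p$mu) - sp$post_mu_init_mean), 3 * se)

  expect_error(initPosterior(sp, integer()), "nonempty")
  # the printed-positive convention is still selectable
  pp <- initPosterior(variationalLayerSpec(post_rho_init_mean = 3,
                                           post_rho_init_sd = 0),
                      4, seed = 1)
  expect_equal(unique(as.numeric(posteriorSigma(pp))), log(1 + exp(3)))
})

test_that("reparameterized sampling is w = mu + softplus(rho) * eps", {
  sp <- variationalLayerSpec()
  p <- initPosterior(sp, c(5, 2), seed = 3)
  # zero noise returns mu exactly
  expect_identical(sampleWeights(p, eps = array(0, c(5, 2))), p$mu)
  # identical eps, identical draw; identical seed, identical draw
  e <- array(rnorm(10), c(5, 2))
  expect_identical(sampleWeights(p, eps = e), sampleWeights(p, eps = e))
  expect_identical(sampleWeights(p, seed = 7), sampleWeights(p, seed = 7))
  expect_false(identical(sampleWeights(p, seed = 7),
                         sampleWeights(p, seed = 8)))
  expect_error(sampleWeights(p, eps = rnorm(3)), "shape")

  # empirical sd over many draws recovers sigma per weight
  p1 <- initPosterior(sp, 10, seed = 4)
  n <- 1e5
  draws <- with(p1, {
    sig <- posteriorSigma(p1)
    set.seed(9)
    matrix(rnorm(10 * n), 10, n) * as.numeric(sig) + as.numeric(mu)
  })
  sig <- as.numeric(posteriorSigma(p1))
  for (i in 1:10) {
    se <- sig[i] / sqrt(2 * (n - 1))   # sd of a sample sd
    expect_lt(abs(sd(draws[i, ]) - sig[i]), 3.5 * se)
  }
})

test_that("closed-form KL matches a numerical-integration oracle", {
  sp <- variationalLayerSpec()
  # identical distributions give exactly zero
  peq <- structure(list(mu = array(0, 1),
                        rho = array(log(exp(0.1) - 1), 1)),
                   class = "variationalPosterior")
  expect_equal(klToPrior(peq, sp), 0, tolerance = 1e-12)
  # frozen 1-D example: mu 0.1, sigma 0.1 against N(0, 0.1) -> 1/2
  p5 <- structure(list(mu = array(0.1, 1),
                       rho = array(log(exp(0.1) - 1), 1)),
                  class = "variationalPosterior")
  expect_equal(klToPrior(p5, sp), 0.5, tolerance = 1e-9)
  expect_equal(kl_numeric(0.1, 0.1, 0, 0.1), 0.5, tolerance = 1e-8)

  # random 1-D posteriors agree with numerical integration to < 1e-6
  set.seed(13)
  for (i in 1:25) {
    mu <- rnorm(1); rho <- rnorm(1, -1, 1)
    p <- structure(list(mu = array(mu, 1), rho = array(rho, 1)),
                   class = "variationalPosterior")
    sig <- log(1 + exp(rho))
    expect_lt(abs(klToPrior(p, sp) - kl_numeric(mu, sig, 0, 0.1)), 1e-6)
  }
})

test_that("KL is nonnegative over many random posteriors", {
  sp <- variationalLayerSpec()
  set.seed(17)
  kls <- replicate(1000, {
    p <- structure(list(mu = array(rnorm(1, 0, 0.5), 1),
                        rho = array(rnorm(1, -2, 1.5), 1)),
                   class = "variationalPosterior")
    klToPrior(p, sp)
  })
  expect_true(all(kls >= 0))
})

test_that("Bayesian conv1d reduces to plain cross-correlation", {
  # identity kernel in posterior-mean mode passes the input through
  id <- structure(list(mu = array(c(0, 1, 0), c(1, 1, 3)),
                       rho = array(-20, c(1, 1, 3))),
                  class = "variationalPosterior")
  x <- array(rnorm(16), c(2, 1, 8))
  out <- bayesConv1d(x, id, stride = 1, padding = 1, sample = FALSE)
  expect_equal(out, x, tolerance = 1e-12)
  # rho -> -inf collapses the stochastic draw onto mu
  out2 <- bayesConv1d(x, id, stride = 1, padding = 1, sample = TRUE,
                      seed = 1)
  expect_equal(out2, x, tolerance = 1e-6)

  # hand-computed cross-correlation, length 8, kernel 3, no padding
  v <- c(1, 2, 3, 4, 5, 4, 3, 2)
  kern <- c(0.5, -1, 2)
  post <- structure(list(mu = array(kern, c(1, 1, 3)),
                         rho = array(-20, c(1, 1, 3))),
                    class = "variationalPosterior")
  got <- bayesConv1d(array(v, c(1, 1, 8)), post, sample = FALSE)
  manual <- vapply(1:6, function(i) sum(v[i:(i + 2)] * kern), numeric(1))
  expect_equal(as.numeric(got), manual, tolerance = 1e-12)

  expect_error(bayesConv1d(array(0, c(1, 2, 8)), post), "channels")
})

test_that("Bayesian linear layer reduces to a matrix product", {
  idp <- structure(list(mu = diag(2), rho = matrix(-20, 2, 2)),
                   class = "variationalPosterior")
  x <- matrix(rnorm(6), 3, 2)
  expect_equal(bayesLinear(x, idp, sample = FALSE), x, tolerance = 1e-12)

  W <- matrix(c(1, 2, 3, 4), 2, 2)
  post <- structure(list(mu = W, rho = matrix(-20, 2, 2)),
                    class = "variationalPosterior")
  got <- bayesLinear(matrix(c(5, 6), 1, 2), post, sample = FALSE)
  expect_equal(as.numeric(got), as.numeric(W %*% c(5, 6)), tolerance = 1e-12)

  # stochastic passes: same seed agrees, different seeds differ
  sp <- variationalLayerSpec()
  p <- initPosterior(sp, c(3, 4), seed = 5)
  xx <- matrix(rnorm(8), 2, 4)
  expect_identical(bayesLinear(xx, p, sample = TRUE, seed = 1),
                   bayesLinear(xx, p, sample = TRUE, seed = 1))
  expect_false(identical(bayesLinear(xx, p, sample = TRUE, seed = 1),
                         bayesLinear(xx, p, sample = TRUE, seed = 2)))
  expect_error(bayesLinear(matrix(0, 2, 3), p), "features")
})
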