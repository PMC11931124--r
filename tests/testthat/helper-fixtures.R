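# Shared fixtures, built in code at test time.

# A tiny architecture that exercises every layer type but runs in
# milliseconds; used by the network unit tests.
tiny_branch <- function(stem_kernel = 3L, attention = "channel") {
  branchConfig(stem_kernel = stem_kernel, stem_out_channels = 4L,
               bottleneck_channels = list(c(4L, 2L, 4L), c(4L, 2L, 6L),
                                          c(6L, 3L, 8L), c(8L, 4L, 8L)),
               bottleneck_strides = c(1L, 2L, 2L, 1L),
               attention = attention)
}

tiny_config <- function(n_classes = 2L, ...) {
  dbayesNetConfig(branch_a = tiny_branch(3L), branch_b = tiny_branch(5L),
                  n_classes = n_classes, ...)
}

# Small labeled SpectrumSet with subject grouping.
tiny_labeled_set <- function(n_sub = 4L, reps = 2L, P = 32L, seed = 99L) {
  set.seed(seed)
  classes <- rep(c("A", "B"), each = n_sub / 2)
  subj <- paste0("s", seq_len(n_sub))
  S <- n_sub * reps
  idx <- rep(seq_len(n_sub), each = reps)
  m <- matrix(rnorm(P * S), P, S) +
    outer(seq_len(P) / P, ifelse(classes[idx] == "B", 2, 0))
  SpectrumSet(seq(500, 2000, length.out = P), m,
              subject_id = subj[idx],
              replicate = rep(seq_len(reps), n_sub),
              label = classes[idx],
              spectrum_id = paste0(subj[idx], "_r", rep(seq_len(reps), n_sub)))
}

# Dense-matrix Whittaker oracle: direct solve with an explicit
# second-difference matrix (independent of the package's sparse path).
dense_whittaker <- function(x, w, lambda) {
  P <- length(x)
  D <- diff(diag(P), differences = 2)
  solve(diag(w) + lambda * crossprod(D), w * x)
}

# Numerical-integration KL oracle for 1-D Gaussians.
kl_numeric <- function(mu, sigma, mu0, sigma0) {
  f <- function(x) {
    q <- stats::dnorm(x, mu, sigma)
    lr <- stats::dnorm(x, mu, sigma, log = TRUE) -
      stats::dnorm(x, mu0, sigma0, log = TRUE)
    q * lr
  }
  stats::integrate(f, mu - 12 * sigma, mu + 12 * sigma,
                   rel.tol = 1e-10)$value
}

# Mann-Whitney pairwise AUC oracle: fraction of (positive, negative) score
# pairs ranked correctly, ties counted half.
auc_pairwise <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
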