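# Internal differentiable operations for the 1-D network. Activations are
# stored channel-first as arrays (C, L, B); the hot kernels (im2col
# convolution and batch normalization, forward and backward) are compiled
# (src/kernels.cpp), the cheap glue (pooling, attention, softmax) stays in
# R. Each *_forward returns the output plus the cache its paired *_backward
# needs.

#' im2col 1-D convolution forward
#' x: (C, L, B); Wm: (C_out, C*k) with input channel fastest; b: length C_out
#' @noRd
conv1d_forward <- function(x, Wm, b, k, stride, pad) {
  d <- dim(x)
  res <- conv1d_fwd_cpp(x, Wm, b, k, stride, pad)
  list(out = res$out, col = res$col,
       geom = list(C = d[1], L = d[2], B = d[3], k = k, stride = stride,
                   pad = pad, Lo = res$Lo))
}

#' Backward of conv1d_forward; returns gradients wrt the flattened weight
#' matrix, bias, and (when need_dx) the input.
#' @noRd
conv1d_backward <- function(dy, col, Wm, geom, need_dx = TRUE) {
  conv1d_bwd_cpp(dy, col, Wm, geom$C, geom$L, geom$B, geom$k, geom$stride,
                 geom$pad, need_dx)
}

#' BatchNorm over (L, B) per channel
#' @noRd
bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1, eps = 1e-5, relu = FALSE) {
  res <- bn_fwd_cpp(x, gamma, beta, run_mean, run_var, train, momentum, eps,
                    relu)
  list(out = res$out,
       cache = list(xhat = res$xhat, invstd = as.numeric(res$invstd),
                    gamma = gamma, beta = beta, train = train, relu = relu),
       run_mean = as.numeric(res$run_mean), run_var = as.numeric(res$run_var))
}

#' @noRd
bn_backward <- function(dy, cache) {
  res <- bn_bwd_cpp(dy, cache$xhat, cache$invstd, cache$gamma, cache$beta,
                    cache$train, cache$relu)
  list(dx = res$dx, dgamma = as.numeric(res$dgamma),
       dbeta = as.numeric(res$dbeta))
}

#' Adaptive average pool to length 1: (C, L, B) -> (C, B)
#' @noRd
gap_forward <- function(x) {
  list(out = gap_fwd_cpp(x), d = dim(x))
}

#' @noRd
gap_backward <- function(dy, d) {
  gap_bwd_cpp(dy, d[2])
}

#' Broadcast a (C, B) per-channel value over length into (C, L, B)
#' @noRd
bcast_len <- function(g, d) {
  aperm(array(as.vector(g), c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' Squeeze-and-excite channel attention on (C, L, B)
#' W1: (Cr, C), W2: (C, Cr) deterministic weights
#' @noRd
se_forward <- function(x, W1, b1, W2, b2) {
  p <- gap_forward(x)            # s: (C, B)
  s <- p$out
  z1 <- W1 %*% s + b1
  h <- z1 * (z1 > 0)
  z2 <- W2 %*% h + b2
  g <- 1 / (1 + exp(-z2))        # (C, B)
  d <- dim(x)
  y <- channel_scale_cpp(x, g)
  list(out = y, cache = list(x = x, s = s, h = h, g = g, mask1 = z1 > 0,
                             W1 = W1, W2 = W2, d = d))
}

#' @noRd
se_backward <- function(dy, cache) {
  d <- cache$d
  dx_direct <- channel_scale_cpp(dy, cache$g)
  # dg: sum over length of x * dy -> (C, B)
  dg <- channel_dot_cpp(cache$x, dy)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(dz2, cache$h)
  db2 <- rowSums(dz2)
  dh <- crossprod(cache$W2, dz2) * cache$mask1
  dW1 <- tcrossprod(dh, cache$s)
  db1 <- rowSums(dh)
  ds <- crossprod(cache$W1, dh)          # (C, B)
  dx_pool <- gap_backward(ds, d)
  list(dx = dx_direct + dx_pool, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Softmax cross-entropy; logits (K, B), labels integer 1..K
#' Returns mean loss over the batch and dlogits.
#' @noRd
softmax_ce <- function(logits, labels) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(B))
  pick <- p[idx]
  loss <- -mean(log(pmax(pick, 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  list(loss = loss, probs = p, dlogits = dlogits)
}

#' Column-wise softmax of a (K, B) logit matrix
#' @noRd
softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  sweep(ex, 2, colSums(ex), "/")
}

#' Standardize spectra against the stored training center/scale
#' x: (1, P, B); center: length-P; scale: scalar
#' @noRd
sweep_center_scale <- function(x, center, scale) {
  d <- dim(x)
  out <- (matrix(x, d[2], d[3]) - center) / scale
  array(out, d)
}
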