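# The dual-branch variational Bayesian 1-D convolutional classifier:
# per branch a BayConv stem, four ResNet-style bottleneck blocks (1x1 reduce
# -> 3 conv -> 1x1 expand, residual add, projection shortcut on shape
# change), optional squeeze-and-excite channel attention, adaptive average
# pooling to one value per channel; pooled features of the two branches are
# concatenated and classified by a BayLinear head. The two branches differ
# (by default in stem kernel size) so they extract features at different
# receptive-field scales.

#' Configuration of one branch
#'
#' @param stem_kernel Odd kernel size of the stem convolution (default 3).
#' @param stem_stride Stem stride (default 2: the stem halves the spectrum
#'   length, like the downsampling stem of ResNet-family encoders).
#' @param stem_out_channels Stem output channels (default 16).
#' @param bottleneck_channels List of exactly 4 `(in, mid, out)` triples;
#'   the default widens 16 -> 32 -> 64 -> 128 with `mid = out/4`.
#' @param bottleneck_strides Integer 4-vector (default `c(2, 2, 2, 2)`).
#' @param pool Only `"adaptive_avg"` (pool to length 1) is supported.
#' @param attention `"channel"` (squeeze-and-excite gate after the fourth
#'   bottleneck; default) or `"none"`.
#' @return A list of class `"branchConfig"`.
#' @export
branchConfig <- function(stem_kernel = 3L, stem_stride = 2L,
                         stem_out_channels = 16L,
                         bottleneck_channels = NULL,
                         bottleneck_strides = c(2L, 2L, 2L, 2L),
                         pool = "adaptive_avg",
                         attention = c("channel", "none")) {
  attention <- match.arg(attention)
  pool <- match.arg(pool, "adaptive_avg")
  stem_kernel <- as.integer(stem_kernel)
  stem_stride <- as.integer(stem_stride)
  if (stem_kernel %% 2 == 0 || stem_kernel < 1) stop("stem_kernel must be odd")
  if (stem_stride < 1) stop("stem_stride must be >= 1")
  if (is.null(bottleneck_channels)) {
    s <- as.integer(stem_out_channels)
    outs <- s * c(1L, 2L, 4L, 8L)
    ins <- c(s, outs[-4])
    bottleneck_channels <- Map(function(i, o) c(i, max(1L, o %/% 4L), o),
                               ins, outs)
  }
  if (length(bottleneck_channels) != 4) {
    stop("exactly 4 bottleneck blocks are required")
  }
  bottleneck_channels <- lapply(bottleneck_channels, function(ch) {
    ch <- as.integer(ch)
    if (length(ch) != 3 || any(ch < 1)) {
      stop("each bottleneck entry must be a positive (in, mid, out) triple")
    }
    ch
  })
  if (bottleneck_channels[[1]][1] != stem_out_channels) {
    stop("first bottleneck input must equal stem_out_channels")
  }
  for (i in 2:4) {
    if (bottleneck_channels[[i]][1] != bottleneck_channels[[i - 1]][3]) {
      stop(sprintf("bottleneck %d input (%d) must equal bottleneck %d output (%d)",
                   i, bottleneck_channels[[i]][1], i - 1,
                   bottleneck_channels[[i - 1]][3]))
    }
  }
  bottleneck_strides <- as.integer(bottleneck_strides)
  if (length(bottleneck_strides) != 4 || any(bottleneck_strides < 1)) {
    stop("bottleneck_strides must be 4 integers >= 1")
  }
  structure(list(stem_kernel = stem_kernel, stem_stride = stem_stride,
                 stem_out_channels = as.integer(stem_out_channels),
                 bottleneck_channels = bottleneck_channels,
                 bottleneck_strides = bottleneck_strides,
                 pool = pool, attention = attention),
            class = "branchConfig")
}

#' Configuration of the full dual-branch model
#'
#' @param branch_a,branch_b [branchConfig()]s; the defaults differ only in
#'   stem kernel (3 vs 7), realizing two receptive-field scales. The two
#'   branches must differ in at least one field (set
#'   `check_distinct = FALSE` only for wiring diagnostics).
#' @param n_classes 2 or 3.
#' @param layer_spec A [variationalLayerSpec()] shared by all Bayesian
#'   layers.
#' @param head_hidden Optional hidden width of the classification head
#'   (default `NULL`: a single BayLinear from concatenated features to
#'   logits).
#' @param check_distinct Enforce branch asymmetry (default `TRUE`).
#' @return A list of class `"dbayesNetConfig"`.
#' @export
dbayesNetConfig <- function(branch_a = branchConfig(stem_kernel = 3L),
                            branch_b = branchConfig(stem_kernel = 7L),
                            n_classes = 2L,
                            layer_spec = variationalLayerSpec(),
                            head_hidden = NULL,
                            check_distinct = TRUE) {
  stopifnot(inherits(branch_a, "branchConfig"),
            inherits(branch_b, "branchConfig"),
            inherits(layer_spec, "variationalLayerSpec"))
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  if (check_distinct && identical(branch_a, branch_b)) {
    stop("branch_a and branch_b must differ in at least one field")
  }
  structure(list(branch_a = branch_a, branch_b = branch_b,
                 n_classes = n_classes, layer_spec = layer_spec,
                 head_hidden = if (is.null(head_hidden)) NULL
                               else as.integer(head_hidden)),
            class = "dbayesNetConfig")
}

#' The DBayesNet model class
#'
#' Holds the architecture configuration, all parameters (variational
#' posteriors for Bayesian layers; plain arrays for batch-norm and attention
#' weights), batch-norm running statistics, and the class labels the model
#' predicts. Build with [buildDBayesNet()], train with [trainDBayesNet()].
#'
#' @slot config A `dbayesNetConfig` list.
#' @slot params Named list of parameters.
#' @slot buffers Named list of batch-norm running statistics.
#' @slot input_length Training input length (the forward pass accepts any
#'   length >= the largest stem kernel thanks to adaptive pooling).
#' @slot classes Character vector of class labels (filled by training).
#' @export
setClass("DBayesNet",
         representation(config = "ANY", params = "list", buffers = "list",
                        input_length = "integer", classes = "character"))

.needs_proj <- function(ch, s) ch[1] != ch[3] || s != 1L

.init_vpost <- function(spec, shape) {
  n <- prod(shape)
  structure(list(
    mu = array(stats::rnorm(n, spec$post_mu_init_mean, spec$post_mu_init_sd),
               dim = shape),
    rho = array(stats::rnorm(n, spec$post_rho_init_mean, spec$post_rho_init_sd),
                dim = shape)),
    class = "variationalPosterior")
}

#' Build a freshly initialized model
#'
#' All Bayesian layers are initialized from `config$layer_spec`; batch-norm
#' scales start at 1 (shifts 0) and attention weights use a scaled-normal
#' init. Initialization is fully determined by `seed`.
#'
#' @param config A [dbayesNetConfig()].
#' @param input_length Length of the training spectra (must be at least the
#'   largest stem kernel).
#' @param seed RNG seed for initialization.
#' @param classes Optional class labels (length `n_classes`).
#' @return A [DBayesNet-class] object.
#' @examples
#' m <- buildDBayesNet(dbayesNetConfig(), input_length = 128, seed = 1)
#' m
#' @export
buildDBayesNet <- function(config = dbayesNetConfig(), input_length,
                           seed = NULL, classes = NULL) {
  stopifnot(inherits(config, "dbayesNetConfig"))
  input_length <- as.integer(input_length)
  kmax <- max(config$branch_a$stem_kernel, config$branch_b$stem_kernel)
  if (input_length < kmax) {
    stop(sprintf("input_length %d is below the largest stem kernel (%d)",
                 input_length, kmax))
  }
  spec <- config$layer_spec
  with_seed(seed, {
    params <- list()
    buffers <- list()
    add_vconv <- function(name, out, inn, k) {
      params[[paste0(name, ".W")]] <<- .init_vpost(spec, c(out, inn, k))
      params[[paste0(name, ".b")]] <<- .init_vpost(spec, out)
    }
    add_bn <- function(name, C) {
      params[[paste0(name, ".gamma")]] <<- rep(1, C)
      params[[paste0(name, ".beta")]] <<- rep(0, C)
      buffers[[paste0(name, ".mean")]] <<- rep(0, C)
      buffers[[paste0(name, ".var")]] <<- rep(1, C)
    }
    add_branch <- function(br, bc) {
      add_vconv(paste0(br, ".stem"), bc$stem_out_channels, 1L, bc$stem_kernel)
      add_bn(paste0(br, ".stem_bn"), bc$stem_out_channels)
      for (i in 1:4) {
        nm <- sprintf("%s.blk%d", br, i)
        ch <- bc$bottleneck_channels[[i]]
        add_vconv(paste0(nm, ".c1"), ch[2], ch[1], 1L)
        add_bn(paste0(nm, ".bn1"), ch[2])
        add_vconv(paste0(nm, ".c2"), ch[2], ch[2], 3L)
        add_bn(paste0(nm, ".bn2"), ch[2])
        add_vconv(paste0(nm, ".c3"), ch[3], ch[2], 1L)
        add_bn(paste0(nm, ".bn3"), ch[3])
        if (.needs_proj(ch, bc$bottleneck_strides[i])) {
          add_vconv(paste0(nm, ".proj"), ch[3], ch[1], 1L)
          add_bn(paste0(nm, ".bnp"), ch[3])
        }
      }
      if (bc$attention == "channel") {
        C <- bc$bottleneck_channels[[4]][3]
        Cr <- max(1L, C %/% 4L)
        params[[paste0(br, ".se.W1")]] <<- matrix(
          stats::rnorm(Cr * C, 0, sqrt(2 / C)), Cr, C)
        params[[paste0(br, ".se.b1")]] <<- rep(0, Cr)
        params[[paste0(br, ".se.W2")]] <<- matrix(
          stats::rnorm(C * Cr, 0, sqrt(2 / Cr)), C, Cr)
        params[[paste0(br, ".se.b2")]] <<- rep(0, C)
      }
    }
    add_branch("a", config$branch_a)
    add_branch("b", config$branch_b)
    feat <- config$branch_a$bottleneck_channels[[4]][3] +
      config$branch_b$bottleneck_channels[[4]][3]
    if (!is.null(config$head_hidden)) {
      params[["head1.W"]] <- .init_vpost(spec, c(config$head_hidden, feat))
      params[["head1.b"]] <- .init_vpost(spec, config$head_hidden)
      params[["head.W"]] <- .init_vpost(spec, c(config$n_classes,
                                                config$head_hidden))
    } else {
      params[["head.W"]] <- .init_vpost(spec, c(config$n_classes, feat))
    }
    params[["head.b"]] <- .init_vpost(spec, config$n_classes)
    methods::new("DBayesNet", config = config, params = params,
                 buffers = buffers, input_length = input_length,
                 classes = classes %||%
                   paste0("class", seq_len(config$n_classes)))
  })
}

# ---- forward / backward engine ------------------------------------------

.vsample <- function(ctx, pname) {
  post <- ctx$params[[pname]]
  if (!ctx$sample) return(post$mu)
  eps <- if (!is.null(ctx$eps_in)) ctx$eps_in[[pname]] else NULL
  if (is.null(eps)) {
    eps <- array(stats::rnorm(length(post$mu)), dim = dim(post$mu))
  }
  ctx$eps[[pname]] <- eps
  post$mu + softplus(post$rho) * eps
}

.acc_vgrad <- function(ctx, pname, dW) {
  post <- ctx$params[[pname]]
  dW <- array(dW, dim = dim(post$mu))
  g <- ctx$grads[[pname]]
  if (is.null(g)) g <- list(mu = 0, rho = 0)
  g$mu <- g$mu + dW
  eps <- ctx$eps[[pname]]
  if (!is.null(eps)) g$rho <- g$rho + dW * eps * sigmoid(post$rho)
  ctx$grads[[pname]] <- g
}

.acc_grad <- function(ctx, pname, d) {
  ctx$grads[[pname]] <- (ctx$grads[[pname]] %||% 0) + d
}

vconv_fw <- function(ctx, name, x, stride, pad) {
  wn <- paste0(name, ".W")
  W <- .vsample(ctx, wn)
  b <- as.numeric(.vsample(ctx, paste0(name, ".b")))
  kd <- dim(ctx$params[[wn]]$mu)
  Wm <- matrix(W, nrow = kd[1])
  res <- conv1d_forward(x, Wm, b, kd[3], stride, pad)
  # 1x1 stride-1 convolutions skip im2col; the input itself backs the
  # weight-gradient product
  ctx$cache[[name]] <- list(col = res$col %||% x, geom = res$geom, Wm = Wm,
                            kd = kd)
  res$out
}

vconv_bw <- function(ctx, name, dy, need_dx = TRUE) {
  cc <- ctx$cache[[name]]
  g <- conv1d_backward(dy, cc$col, cc$Wm, cc$geom, need_dx = need_dx)
  .acc_vgrad(ctx, paste0(name, ".W"), g$dW)
  .acc_vgrad(ctx, paste0(name, ".b"), g$db)
  g$dx
}

bnorm_fw <- function(ctx, name, x, relu = FALSE) {
  res <- bn_forward(x, ctx$params[[paste0(name, ".gamma")]],
                    ctx$params[[paste0(name, ".beta")]],
                    ctx$buffers[[paste0(name, ".mean")]],
                    ctx$buffers[[paste0(name, ".var")]],
                    ctx$train, momentum = ctx$bn_momentum, relu = relu)
  ctx$new_buffers[[paste0(name, ".mean")]] <- res$run_mean
  ctx$new_buffers[[paste0(name, ".var")]] <- res$run_var
  ctx$cache[[name]] <- res$cache
  res$out
}

bnorm_bw <- function(ctx, name, dy) {
  g <- bn_backward(dy, ctx$cache[[name]])
  .acc_grad(ctx, paste0(name, ".gamma"), g$dgamma)
  .acc_grad(ctx, paste0(name, ".beta"), g$dbeta)
  g$dx
}

relu_fw <- function(ctx, name, x) {
  ctx$cache[[name]] <- x
  if (length(dim(x)) == 3) relu_fwd_cpp(x) else x * (x > 0)
}

relu_bw <- function(ctx, name, dy) {
  ref <- ctx$cache[[name]]
  if (length(dim(ref)) == 3) masked_mul_cpp(dy, ref) else dy * (ref > 0)
}

se_fw <- function(ctx, name, x) {
  res <- se_forward(x, ctx$params[[paste0(name, ".W1")]],
                    ctx$params[[paste0(name, ".b1")]],
                    ctx$params[[paste0(name, ".W2")]],
                    ctx$params[[paste0(name, ".b2")]])
  ctx$cache[[name]] <- res$cache
  res$out
}

se_bw <- function(ctx, name, dy) {
  g <- se_backward(dy, ctx$cache[[name]])
  .acc_grad(ctx, paste0(name, ".W1"), g$dW1)
  .acc_grad(ctx, paste0(name, ".b1"), g$db1)
  .acc_grad(ctx, paste0(name, ".W2"), g$dW2)
  .acc_grad(ctx, paste0(name, ".b2"), g$db2)
  g$dx
}

vlinear_fw <- function(ctx, name, x) {
  # x: (F, B) -> (out, B)
  W <- .vsample(ctx, paste0(name, ".W"))
  b <- as.numeric(.vsample(ctx, paste0(name, ".b")))
  ctx$cache[[name]] <- list(x = x, W = W)
  W %*% x + b
}

vlinear_bw <- function(ctx, name, dy) {
  cc <- ctx$cache[[name]]
  .acc_vgrad(ctx, paste0(name, ".W"), tcrossprod(dy, cc$x))
  .acc_vgrad(ctx, paste0(name, ".b"), rowSums(dy))
  crossprod(cc$W, dy)
}

block_fw <- function(ctx, br, i, bc, x) {
  nm <- sprintf("%s.blk%d", br, i)
  ch <- bc$bottleneck_channels[[i]]
  s <- bc$bottleneck_strides[i]
  h <- vconv_fw(ctx, paste0(nm, ".c1"), x, 1L, 0L)
  h <- bnorm_fw(ctx, paste0(nm, ".bn1"), h, relu = TRUE)
  h <- vconv_fw(ctx, paste0(nm, ".c2"), h, s, 1L)
  h <- bnorm_fw(ctx, paste0(nm, ".bn2"), h, relu = TRUE)
  h <- vconv_fw(ctx, paste0(nm, ".c3"), h, 1L, 0L)
  h <- bnorm_fw(ctx, paste0(nm, ".bn3"), h)
  sc <- if (.needs_proj(ch, s)) {
    p <- vconv_fw(ctx, paste0(nm, ".proj"), x, s, 0L)
    bnorm_fw(ctx, paste0(nm, ".bnp"), p)
  } else x
  y <- h + sc
  ctx$cache[[paste0(nm, ".add")]] <- y
  relu_fwd_cpp(y)
}

block_bw <- function(ctx, br, i, bc, dy) {
  nm <- sprintf("%s.blk%d", br, i)
  ch <- bc$bottleneck_channels[[i]]
  s <- bc$bottleneck_strides[i]
  dy <- masked_mul_cpp(dy, ctx$cache[[paste0(nm, ".add")]])
  dx_sc <- if (.needs_proj(ch, s)) {
    dp <- bnorm_bw(ctx, paste0(nm, ".bnp"), dy)
    vconv_bw(ctx, paste0(nm, ".proj"), dp)
  } else dy
  dh <- bnorm_bw(ctx, paste0(nm, ".bn3"), dy)
  dh <- vconv_bw(ctx, paste0(nm, ".c3"), dh)
  dh <- bnorm_bw(ctx, paste0(nm, ".bn2"), dh)
  dh <- vconv_bw(ctx, paste0(nm, ".c2"), dh)
  dh <- bnorm_bw(ctx, paste0(nm, ".bn1"), dh)
  dx <- vconv_bw(ctx, paste0(nm, ".c1"), dh)
  dx + dx_sc
}

branch_fw <- function(ctx, br, bc, x) {
  x <- vconv_fw(ctx, paste0(br, ".stem"), x, bc$stem_stride,
                (bc$stem_kernel - 1L) %/% 2L)
  x <- bnorm_fw(ctx, paste0(br, ".stem_bn"), x, relu = TRUE)
  for (i in 1:4) x <- block_fw(ctx, br, i, bc, x)
  if (bc$attention == "channel") x <- se_fw(ctx, paste0(br, ".se"), x)
  p <- gap_forward(x)
  ctx$cache[[paste0(br, ".gap")]] <- p$d
  p$out
}

branch_bw <- function(ctx, br, bc, dpool) {
  dx <- gap_backward(dpool, ctx$cache[[paste0(br, ".gap")]])
  if (bc$attention == "channel") dx <- se_bw(ctx, paste0(br, ".se"), dx)
  for (i in 4:1) dx <- block_bw(ctx, br, i, bc, dx)
  dx <- bnorm_bw(ctx, paste0(br, ".stem_bn"), dx)
  # the spectrum-level input gradient is never consumed
  vconv_bw(ctx, paste0(br, ".stem"), dx, need_dx = FALSE)
}

#' Full-network forward pass (internal)
#' x: (1, P, B); returns logits (K, B) and the pass context.
#' @noRd
nn_forward <- function(model, x, sample, train, eps_list = NULL,
                       bn_momentum = 0.1) {
  ctr <- model@buffers[["input.center"]]
  if (!is.null(ctr)) {
    if (dim(x)[2] != length(ctr)) {
      stop(sprintf(
        "model was trained on %d-point spectra but input has %d points",
        length(ctr), dim(x)[2]))
    }
    x <- sweep_center_scale(x, ctr, model@buffers[["input.scale"]])
  }
  ctx <- new.env(parent = emptyenv())
  ctx$params <- model@params
  ctx$buffers <- model@buffers
  ctx$new_buffers <- model@buffers
  ctx$cache <- list()
  ctx$eps <- list()
  ctx$eps_in <- eps_list
  ctx$sample <- sample
  ctx$train <- train
  ctx$bn_momentum <- bn_momentum
  cfg <- model@config
  fa <- branch_fw(ctx, "a", cfg$branch_a, x)
  fb <- branch_fw(ctx, "b", cfg$branch_b, x)
  feat <- rbind(fa, fb)
  if (!is.null(cfg$head_hidden)) {
    feat <- relu_fw(ctx, "head1_relu", vlinear_fw(ctx, "head1", feat))
  }
  logits <- vlinear_fw(ctx, "head", feat)
  list(logits = logits, ctx = ctx, split = nrow(fa),
       features = list(a = fa, b = fb))
}

#' Full-network backward pass (internal); returns the gradient list.
#' @noRd
nn_backward <- function(model, fwd, dlogits) {
  ctx <- fwd$ctx
  ctx$grads <- list()
  cfg <- model@config
  dfeat <- vlinear_bw(ctx, "head", dlogits)
  if (!is.null(cfg$head_hidden)) {
    dfeat <- vlinear_bw(ctx, "head1", relu_bw(ctx, "head1_relu", dfeat))
  }
  da <- dfeat[seq_len(fwd$split), , drop = FALSE]
  db <- dfeat[-seq_len(fwd$split), , drop = FALSE]
  dxa <- branch_bw(ctx, "a", cfg$branch_a, da)
  dxb <- branch_bw(ctx, "b", cfg$branch_b, db)
  list(grads = ctx$grads, dx = dxa + dxb)
}

#' Draw one standard-normal noise tensor per variational parameter,
#' consuming the RNG in the forward sampling order
#' @noRd
draw_eps <- function(params) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (inherits(p, "variationalPosterior")) {
      out[[nm]] <- array(stats::rnorm(length(p$mu)), dim = dim(p$mu))
    }
  }
  out
}

#' Recompute batch-norm running statistics for one weight draw
#'
#' The normalization statistics are a function of the network weights, so a
#' sampled network is completed by re-estimating them (cumulative average
#' over the stored calibration spectra) under that draw. Returns the
#' existing buffers untouched when no calibration spectra are stored.
#' @noRd
recalibrate_buffers <- function(model, eps_list = NULL) {
  calib <- model@buffers[["calib.spectra"]]
  if (is.null(calib)) return(model@buffers)
  x <- array(calib, c(1L, nrow(calib), ncol(calib)))
  N <- ncol(calib)
  n_chunks <- max(1L, ceiling(N / 96L))
  idx_list <- split(seq_len(N), rep_len(seq_len(n_chunks), N))
  buffers <- model@buffers
  for (i in seq_along(idx_list)) {
    model@buffers <- buffers
    fwd <- nn_forward(model, x[, , idx_list[[i]], drop = FALSE],
                      sample = !is.null(eps_list), train = TRUE,
                      eps_list = eps_list, bn_momentum = 1 / i)
    buffers <- as.list(fwd$ctx$new_buffers)
  }
  buffers
}

#' Coerce spectra to the (1, P, B) input array
#' @noRd
as_input_array <- function(x) {
  if (methods::is(x, "SpectrumSet")) x <- intensities(x)
  if (is.matrix(x)) {                      # P x B
    array(x, dim = c(1L, nrow(x), ncol(x)))
  } else if (length(dim(x)) == 3) {        # B x 1 x P (user-facing layout)
    if (dim(x)[2] != 1) stop("spectra have a single input channel")
    aperm(x, c(2, 3, 1))
  } else stop("cannot interpret input spectra")
}

#' Compute class logits
#'
#' Runs the network forward in posterior-mean mode (`sample = FALSE`,
#' deterministic and identical across calls) or with a reparameterized
#' posterior draw (`sample = TRUE`; reproducible under `seed`). Batch-norm
#' uses running statistics (evaluation mode).
#'
#' @param model A trained (or fresh) [DBayesNet-class].
#' @param x A [SpectrumSet-class], a P x B intensity matrix, or a
#'   `B x 1 x P` array.
#' @param sample Stochastic weights? Default `FALSE`.
#' @param seed Seed for the stochastic draw.
#' @return A B x n_classes matrix of logits.
#' @export
predictLogits <- function(model, x, sample = FALSE, seed = NULL) {
  stopifnot(methods::is(model, "DBayesNet"))
  xin <- as_input_array(x)
  out <- with_seed(seed, nn_forward(model, xin, sample = sample,
                                    train = FALSE))
  lg <- t(out$logits)
  colnames(lg) <- model@classes
  lg
}

#' Per-layer and total KL divergence of the weight posterior
#'
#' `modelKL()` returns the sum over every variational layer of the
#' closed-form Gaussian KL to the shared prior; `layerKL()` the named
#' per-tensor decomposition (their sum equals `modelKL()` exactly).
#'
#' @param model A [DBayesNet-class].
#' @return Scalar (`modelKL`) or named numeric vector (`layerKL`).
#' @export
modelKL <- function(model) {
  sum(layerKL(model))
}

#' @rdname modelKL
#' @export
layerKL <- function(model) {
  stopifnot(methods::is(model, "DBayesNet"))
  spec <- model@config$layer_spec
  isv <- vapply(model@params, inherits, logical(1), "variationalPosterior")
  vapply(model@params[isv], klToPrior, numeric(1), spec = spec)
}

#' Number of trainable scalars (mu and rho count separately)
#' @noRd
n_model_params <- function(model) {
  sum(vapply(model@params, function(p) {
    if (inherits(p, "variationalPosterior")) 2L * length(p$mu)
    else length(p)
  }, integer(1)))
}

setMethod("show", "DBayesNet", function(object) {
  cfg <- object@config
  cat("DBayesNet:", cfg$n_classes, "classes,",
      format(n_model_params(object), big.mark = ","), "trainable scalars\n")
  cat(sprintf("  branch A: stem k=%d, widths %s, attention %s\n",
              cfg$branch_a$stem_kernel,
              paste(vapply(cfg$branch_a$bottleneck_channels, `[`, integer(1), 3),
                    collapse = "-"),
              cfg$branch_a$attention))
  cat(sprintf("  branch B: stem k=%d, widths %s, attention %s\n",
              cfg$branch_b$stem_kernel,
              paste(vapply(cfg$branch_b$bottleneck_channels, `[`, integer(1), 3),
                    collapse = "-"),
              cfg$branch_b$attention))
  cat(sprintf("  KL(q || prior) = %.4g\n", modelKL(object)))
  invisible(NULL)
})

#' Save / load a model checkpoint
#'
#' The checkpoint stores the full parameter set (all mu/rho tensors),
#' batch-norm statistics, configuration and class labels; reloading
#' reproduces posterior-mean logits bit-identically.
#'
#' @param model A [DBayesNet-class].
#' @param path Checkpoint file path.
#' @return `loadCheckpoint()` returns the restored [DBayesNet-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(methods::is(model, "DBayesNet"))
  saveRDS(list(format = "DBayesNet-checkpoint-1",
               config = model@config, params = model@params,
               buffers = model@buffers, input_length = model@input_length,
               classes = model@classes), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "DBayesNet-checkpoint-1")) {
    stop("not a DBayesNet checkpoint: ", path)
  }
  methods::new("DBayesNet", config = obj$config, params = obj$params,
               buffers = obj$buffers, input_length = obj$input_length,
               classes = obj$classes)
}
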