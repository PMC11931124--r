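# ELBO training of the dual-branch Bayesian network, with subject-grouped
# data splitting. The objective per minibatch is
#   cross-entropy(logits, labels) + beta * KL(q || prior) / n_minibatches,
# with one reparameterized weight sample per forward pass (optionally
# averaged over mc_train_samples draws), optimized by Adam.

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 100).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param kl_weight Beta weight on the KL term (>= 0, default 1).
#' @param kl_warmup_epochs Linearly ramp beta from 0 over this many epochs
#'   (default 0: no warm-up).
#' @param mc_train_samples Weight draws averaged per gradient step (default 1).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Seed controlling shuffling and weight sampling.
#' @param train_frac,test_frac Subject-grouped split fractions (must sum
#'   to 1; defaults 0.8 / 0.2).
#' @param early_stop_patience Stop when the epoch training loss has not
#'   improved for this many epochs (`NULL`, the default, disables).
#' @return A list of class `"trainConfig"`.
#' @export
trainConfig <- function(epochs = 100L, batch_size = 16L,
                        learning_rate = 1e-3, kl_weight = 1,
                        kl_warmup_epochs = 0L, mc_train_samples = 1L,
                        optimizer = c("adam", "sgd"), seed = 1L,
                        train_frac = 0.8, test_frac = 0.2,
                        early_stop_patience = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            kl_weight >= 0, mc_train_samples >= 1)
  if (abs(train_frac + test_frac - 1) > 1e-8) {
    stop("train_frac + test_frac must equal 1")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 mc_train_samples = as.integer(mc_train_samples),
                 optimizer = optimizer, seed = seed,
                 train_frac = train_frac, test_frac = test_frac,
                 early_stop_patience = early_stop_patience),
            class = "trainConfig")
}

#' Subject-grouped stratified train/test split
#'
#' Every subject's replicate spectra land wholly in one partition (the
#' replicates of one serum sample are strongly correlated, so splitting them
#' across partitions would leak), and the split is stratified: within each
#' class, `round(test_frac * n_subjects)` subjects go to the test side.
#'
#' @param x A labeled [SpectrumSet-class].
#' @param train_frac,test_frac Fractions summing to 1.
#' @param seed Seed for the subject shuffle.
#' @return A list with [SpectrumSet-class] elements `train` and `test`.
#' @export
splitBySubject <- function(x, train_frac = 0.8, test_frac = 1 - train_frac,
                           seed = NULL) {
  stopifnot(methods::is(x, "SpectrumSet"))
  if (abs(train_frac + test_frac - 1) > 1e-8) {
    stop("train_frac + test_frac must equal 1")
  }
  info <- spectrumInfo(x)
  if (all(is.na(info$label))) stop("labels are required for splitting")
  subj <- unique(info[, c("subject_id", "label")])
  if (anyDuplicated(subj$subject_id)) {
    stop("a subject carries more than one class label")
  }
  counts <- table(subj$label)
  if (any(counts < 2)) {
    stop("every class needs at least 2 subjects to split: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  with_seed(seed, {
    test_subjects <- unlist(lapply(split(subj$subject_id, subj$label),
                                   function(ids) {
      ids <- sample(ids)
      n_test <- max(1L, round(test_frac * length(ids)))
      if (n_test >= length(ids)) n_test <- length(ids) - 1L
      ids[seq_len(n_test)]
    }), use.names = FALSE)
    in_test <- info$subject_id %in% test_subjects
    list(train = x[, !in_test], test = x[, in_test])
  })
}

#' Minibatch evidence-lower-bound loss
#'
#' `cross-entropy(logits, labels) + beta * kl / n_minibatches`, with the
#' cross-entropy averaged over the batch. With `beta = 0` this is plain
#' cross-entropy.
#'
#' @param logits B x K matrix.
#' @param labels Integer class indices (1..K) or a factor of length B.
#' @param kl Scalar KL divergence of the weight posterior.
#' @param beta KL weight (default 1).
#' @param n_minibatches Minibatches per epoch used for KL scaling.
#' @return Scalar loss.
#' @export
elboLoss <- function(logits, labels, kl = 0, beta = 1, n_minibatches = 1) {
  logits <- as.matrix(logits)
  labels <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  stopifnot(length(labels) == nrow(logits), all(labels >= 1),
            all(labels <= ncol(logits)))
  ce <- softmax_ce(t(logits), labels)$loss
  ce + beta * kl / n_minibatches
}

#' KL gradients wrt mu and rho for every variational parameter
#' @noRd
.kl_grads <- function(params, spec, scale) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!inherits(p, "variationalPosterior")) next
    sigma <- softplus(p$rho)
    out[[nm]] <- list(
      mu = scale * (p$mu - spec$prior_mu) / spec$prior_sigma^2,
      rho = scale * (sigma / spec$prior_sigma^2 - 1 / sigma) * sigmoid(p$rho))
  }
  out
}

.flatten_grads <- function(params, grads) {
  # one flat numeric-update view per parameter entry, keyed "name" or
  # "name@mu"/"name@rho" for posteriors
  out <- list()
  for (nm in names(grads)) {
    if (inherits(params[[nm]], "variationalPosterior")) {
      out[[paste0(nm, "@mu")]] <- grads[[nm]]$mu
      out[[paste0(nm, "@rho")]] <- grads[[nm]]$rho
    } else {
      out[[nm]] <- grads[[nm]]
    }
  }
  out
}

.get_param_view <- function(params, key) {
  if (grepl("@", key, fixed = TRUE)) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]]
  } else params[[key]]
}

.set_param_view <- function(params, key, value) {
  if (grepl("@", key, fixed = TRUE)) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]] <- value
  } else params[[key]] <- value
  params
}

#' Train a DBayesNet by stochastic ELBO minimization
#'
#' Runs minibatch gradient descent on the ELBO with one (or
#' `mc_train_samples`) reparameterized weight draw per forward pass. The
#' whole run — shuffling, weight noise, everything — is determined by
#' `cfg$seed`. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A [DBayesNet-class] (see [buildDBayesNet()]).
#' @param train_set A labeled, preprocessed [SpectrumSet-class] whose point
#'   count matches `model@input_length`.
#' @param cfg A [trainConfig()].
#' @param verbose Print an epoch summary every 10 epochs.
#' @return A list with `model` (trained) and `history` (data.frame of
#'   per-epoch `loss`, `ce`, `kl`, `accuracy`).
#' @export
trainDBayesNet <- function(model, train_set, cfg = trainConfig(),
                           verbose = FALSE) {
  stopifnot(methods::is(model, "DBayesNet"),
            methods::is(train_set, "SpectrumSet"),
            inherits(cfg, "trainConfig"))
  lab <- droplevels(classLabels(train_set))
  if (anyNA(lab)) stop("training spectra must all carry labels")
  classes <- levels(lab)
  if (length(classes) != model@config$n_classes) {
    stop(sprintf("model expects %d classes but data has %d",
                 model@config$n_classes, length(classes)))
  }
  model@classes <- classes
  y <- as.integer(lab)
  xall <- as_input_array(train_set)       # (1, P, N)
  N <- dim(xall)[3]
  if (dim(xall)[2] != model@input_length) {
    stop(sprintf("spectra have %d points but the model was built for %d",
                 dim(xall)[2], model@input_length))
  }
  # Input standardization, stored with the model: spectra are centered on
  # the training-set mean spectrum and scaled by one global standard
  # deviation. Serum spectra share a dominant common profile; removing it
  # keeps the batch-norm statistics stable across stochastic weight draws
  # (a per-draw offset proportional to the common profile would otherwise
  # swamp the small between-spectrum variation).
  # The scale is the plain global standard deviation of the training
  # matrix (not of the centered residuals): batch normalization makes the
  # network invariant to this constant on in-distribution data, but it
  # bounds the image of degenerate inputs — a blank spectrum standardizes
  # to about -center/scale, which stays O(1) instead of tens of standard
  # deviations away, so a forward pass on such inputs cannot saturate.
  ctr <- rowMeans(intensities(train_set))
  sc <- stats::sd(intensities(train_set))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  model@buffers[["input.center"]] <- ctr
  model@buffers[["input.scale"]] <- sc

  spec <- model@config$layer_spec
  n_batches <- ceiling(N / cfg$batch_size)
  params <- model@params
  buffers <- model@buffers
  opt_state <- list(t = 0)
  lr <- cfg$learning_rate
  history <- data.frame(epoch = integer(), loss = numeric(), ce = numeric(),
                        kl = numeric(), accuracy = numeric())
  best <- Inf; since_best <- 0L

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      beta <- cfg$kl_weight
      if (cfg$kl_warmup_epochs > 0) {
        beta <- beta * min(1, epoch / cfg$kl_warmup_epochs)
      }
      ord <- sample.int(N)
      ep_ce <- 0; ep_loss <- 0; ep_correct <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, N)]
        xb <- xall[, , idx, drop = FALSE]
        yb <- y[idx]
        acc_grads <- NULL
        ce_b <- 0
        mdl <- methods::new("DBayesNet", config = model@config,
                            params = params, buffers = buffers,
                            input_length = model@input_length,
                            classes = classes)
        for (s in seq_len(cfg$mc_train_samples)) {
          fwd <- nn_forward(mdl, xb, sample = TRUE, train = TRUE)
          sm <- softmax_ce(fwd$logits, yb)
          bwd <- nn_backward(mdl, fwd, sm$dlogits)
          ce_b <- ce_b + sm$loss
          acc_grads <- if (is.null(acc_grads)) bwd$grads
                       else .merge_grads(acc_grads, bwd$grads)
          if (s == cfg$mc_train_samples) buffers <- as.list(fwd$ctx$new_buffers)
          if (s == 1) {
            pred <- max.col(t(fwd$logits))
            ep_correct <- ep_correct + sum(pred == yb)
          }
        }
        ce_b <- ce_b / cfg$mc_train_samples
        if (cfg$mc_train_samples > 1) {
          acc_grads <- .scale_grads(acc_grads, 1 / cfg$mc_train_samples)
        }
        kl <- modelKL(mdl)
        # per-datapoint ELBO: the cross-entropy term is a batch mean, so
        # the matching KL share is KL / N (dividing by the minibatch count
        # alone would overweight the prior by a factor of the batch size)
        loss <- ce_b + beta * kl / N
        if (!is.finite(loss)) {
          stop(sprintf(
            "non-finite loss at epoch %d batch %d (ce = %.4g, kl = %.4g)",
            epoch, bi, ce_b, kl))
        }
        # The mu part of the KL gradient is applied decoupled from Adam
        # (exactly the way AdamW decouples weight decay, of which it is
        # the Gaussian-prior analogue): folded into the adaptive moments,
        # Adam would normalize the small, perfectly consistent prior pull
        # up to full-size steps on every weight and drown the data
        # signal. The rho part stays inside Adam: it is not a decay but
        # the restoring force that carries each weight's scale to its
        # variational optimum (the prior scale wherever the data are
        # uninformative), and without adaptive scaling it would need
        # thousands of epochs to get there.
        klg <- .kl_grads(params, spec, beta / N)
        for (nm in names(klg)) {
          g <- acc_grads[[nm]] %||% list(mu = 0, rho = 0)
          g$rho <- g$rho + klg[[nm]]$rho
          acc_grads[[nm]] <- g
        }
        flat <- .flatten_grads(params, acc_grads)
        if (cfg$optimizer == "adam") {
          opt_state$t <- opt_state$t + 1
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          corr1 <- 1 - b1^opt_state$t
          corr2 <- 1 - b2^opt_state$t
          for (key in names(flat)) {
            g <- flat[[key]]
            m <- opt_state$m[[key]] %||% 0
            v <- opt_state$v[[key]] %||% 0
            m <- b1 * m + (1 - b1) * g
            v <- b2 * v + (1 - b2) * g^2
            opt_state$m[[key]] <- m
            opt_state$v[[key]] <- v
            step <- lr * (m / corr1) / (sqrt(v / corr2) + eps)
            params <- .set_param_view(params, key,
                                      .get_param_view(params, key) - step)
          }
        } else {
          for (key in names(flat)) {
            params <- .set_param_view(
              params, key, .get_param_view(params, key) - lr * flat[[key]])
          }
        }
        for (nm in names(klg)) {
          p <- params[[nm]]
          p$mu <- p$mu - lr * klg[[nm]]$mu
          params[[nm]] <- p
        }
        ep_ce <- ep_ce + ce_b * length(idx)
        ep_loss <- ep_loss + loss * length(idx)
      }
      mdl_kl <- modelKL(methods::new("DBayesNet", config = model@config,
                                     params = params, buffers = buffers,
                                     input_length = model@input_length,
                                     classes = classes))
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / N, ce = ep_ce / N, kl = mdl_kl,
        accuracy = ep_correct / N))
      if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
        message(sprintf("epoch %3d  loss %.4f  ce %.4f  acc %.3f",
                        epoch, ep_loss / N, ep_ce / N, ep_correct / N))
      }
      if (!is.null(cfg$early_stop_patience)) {
        if (ep_loss / N < best - 1e-8) {
          best <- ep_loss / N; since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$early_stop_patience) break
        }
      }
    }
  })
  # Recalibrate the batch-norm running statistics under the posterior-mean
  # weights: during training the statistics are accumulated under sampled
  # weights, whose draw-to-draw variation biases them relative to any one
  # forward mode. A cumulative-average pass over the training set (no
  # sampling, no updates to the weights) aligns them with the
  # posterior-mean network used as the reference at evaluation.
  mdl <- methods::new("DBayesNet", config = model@config, params = params,
                      buffers = buffers, input_length = model@input_length,
                      classes = classes)
  chunk <- 96L
  n_chunks <- max(1L, ceiling(N / chunk))
  # round-robin chunks so each mixes the (class-blocked) spectra
  idx_list <- split(seq_len(N), rep_len(seq_len(n_chunks), N))
  for (i in seq_along(idx_list)) {
    mdl@buffers <- buffers
    fwd <- nn_forward(mdl, xall[, , idx_list[[i]], drop = FALSE],
                      sample = FALSE, train = TRUE, bn_momentum = 1 / i)
    buffers <- as.list(fwd$ctx$new_buffers)
  }

  # the training spectra double as the normalization-calibration set for
  # Monte-Carlo prediction (see mcPredict)
  buffers[["calib.spectra"]] <- intensities(train_set)

  model@params <- params
  model@buffers <- buffers
  list(model = model, history = history)
}

.merge_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) { a[[nm]] <- b[[nm]]; next }
    if (is.list(b[[nm]])) {
      a[[nm]]$mu <- a[[nm]]$mu + b[[nm]]$mu
      a[[nm]]$rho <- a[[nm]]$rho + b[[nm]]$rho
    } else {
      a[[nm]] <- a[[nm]] + b[[nm]]
    }
  }
  a
}

.scale_grads <- function(g, f) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      g[[nm]]$mu <- g[[nm]]$mu * f
      g[[nm]]$rho <- g[[nm]]$rho * f
    } else {
      g[[nm]] <- g[[nm]] * f
    }
  }
  g
}
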