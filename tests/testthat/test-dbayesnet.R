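test_that("configs validate the architectural contract", {
  expect_error(branchConfig(stem_kernel = 4), "odd")
  expect_error(branchConfig(bottleneck_channels = list(c(16, 4, 16))),
               "exactly 4")
  expect_error(branchConfig(bottleneck_channels = list(
    c(16, 4, 16), c(32, 8, 32), c(32, 16, 64), c(64, 32, 128))),
    "must equal")
  expect_error(dbayesNetConfig(tiny_branch(3), tiny_branch(3)),
               "differ")
  expect_error(dbayesNetConfig(n_classes = 5), "2 or 3")
  # identical branches are allowed only for explicit wiring diagnostics
  cfg <- dbayesNetConfig(tiny_branch(3), tiny_branch(3),
                         check_distinct = FALSE)
  expect_s4_class(buildDBayesNet(cfg, 64, seed = 1), "DBayesNet")
})

test_that("the built model matches the two-branch bottleneck topology", {
  m <- buildDBayesNet(tiny_config(), input_length = 64, seed = 1)
  nms <- names(m@params)
  for (br in c("a", "b")) {
    blocks <- unique(sub("^([ab]\\.blk[0-9]+)\\..*$", "\\1",
                         grep(paste0("^", br, "\\.blk"), nms, value = TRUE)))
    expect_length(blocks, 4L)        # exactly 4 bottlenecks per branch
    expect_true(paste0(br, ".stem.W") %in% nms)
    expect_true(paste0(br, ".se.W1") %in% nms)
  }
  expect_true("head.W" %in% nms)

  # logits shape contract: batch of 5, 2 classes
  x <- matrix(rnorm(64 * 5), 64, 5)
  lg <- predictLogits(m, x)
  expect_equal(dim(lg), c(5L, 2L))

  m3 <- buildDBayesNet(tiny_config(n_classes = 3), 64, seed = 1)
  expect_equal(dim(predictLogits(m3, x)), c(5L, 3L))
})

test_that("model KL is the sum of per-layer KLs and vanishes at the prior", {
  m <- buildDBayesNet(tiny_config(), input_length = 64, seed = 2)
  per <- layerKL(m)
  expect_gt(modelKL(m), 0)
  expect_equal(modelKL(m), sum(per), tolerance = 1e-12)
  # forcing every posterior onto the prior zeroes the KL
  sp <- m@config$layer_spec
  rho0 <- log(exp(sp$prior_sigma) - 1)
  for (nm in names(m@params)) {
    p <- m@params[[nm]]
    if (inherits(p, "variationalPosterior")) {
      p$mu[] <- sp$prior_mu
      p$rho[] <- rho0
      m@params[[nm]] <- p
    }
  }
  expect_equal(modelKL(m), 0, tolerance = 1e-9)
})

test_that("forward passes are deterministic exactly when they should be", {
  m <- buildDBayesNet(tiny_config(), input_length = 64, seed = 3)
  x <- matrix(rnorm(64 * 4), 64, 4)
  expect_identical(predictLogits(m, x), predictLogits(m, x))
  expect_identical(predictLogits(m, x, sample = TRUE, seed = 11),
                   predictLogits(m, x, sample = TRUE, seed = 11))
  expect_false(identical(predictLogits(m, x, sample = TRUE, seed = 11),
                         predictLogits(m, x, sample = TRUE, seed = 12)))
  # all-zero input stays finite
  lg <- predictLogits(m, matrix(0, 64, 3))
  expect_true(all(is.finite(lg)))
})

test_that("adaptive pooling makes the forward length-agnostic", {
  m <- buildDBayesNet(tiny_config(), input_length = 1501, seed = 4)
  for (L in c(64, 500, 1501)) {
    lg <- predictLogits(m, matrix(rnorm(L * 2), L, 2))
    expect_equal(dim(lg), c(2L, 2L))
    expect_true(all(is.finite(lg)))
  }
})

test_that("identical tied branches duplicate the concatenated features", {
  cfg <- dbayesNetConfig(tiny_branch(3), tiny_branch(3),
                         check_distinct = FALSE)
  m <- buildDBayesNet(cfg, input_length = 64, seed = 5)
  # tie branch b's parameters and buffers to branch a's
  for (nm in grep("^a\\.", names(m@params), value = TRUE)) {
    m@params[[sub("^a", "b", nm)]] <- m@params[[nm]]
  }
  for (nm in grep("^a\\.", names(m@buffers), value = TRUE)) {
    m@buffers[[sub("^a", "b", nm)]] <- m@buffers[[nm]]
  }
  x <- array(rnorm(64 * 3), c(1, 64, 3))
  fwd <- DBayesNet:::nn_forward(m, x, sample = FALSE, train = FALSE)
  expect_equal(fwd$features$a, fwd$features$b, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences on a tiny model", {
  m <- buildDBayesNet(tiny_config(), input_length = 24, seed = 11)
  ns <- asNamespace("DBayesNet")
  set.seed(42)
  x <- array(rnorm(24 * 3), c(1, 24, 3))
  y <- c(1L, 2L, 1L)
  fwd0 <- ns$nn_forward(m, x, sample = TRUE, train = TRUE)
  eps <- fwd0$ctx$eps
  loss_fn <- function(model) {
    f <- ns$nn_forward(model, x, sample = TRUE, train = TRUE, eps_list = eps)
    ns$softmax_ce(f$logits, y)$loss
  }
  fwd <- ns$nn_forward(m, x, sample = TRUE, train = TRUE, eps_list = eps)
  g <- ns$nn_backward(m, fwd, ns$softmax_ce(fwd$logits, y)$dlogits)$grads
  h <- 1e-5
  set.seed(7)
  for (nm in sample(names(g), 12)) {
    p <- m@params[[nm]]
    flds <- if (inherits(p, "variationalPosterior")) c("mu", "rho") else NA
    for (fld in flds) {
      n <- if (is.na(fld)) length(p) else length(p[[fld]])
      for (ii in sample(n, min(2, n))) {
        m2 <- m; m3 <- m
        if (is.na(fld)) {
          m2@params[[nm]][ii] <- m2@params[[nm]][ii] + h
          m3@params[[nm]][ii] <- m3@params[[nm]][ii] - h
          ana <- g[[nm]][ii]
        } else {
          m2@params[[nm]][[fld]][ii] <- m2@params[[nm]][[fld]][ii] + h
          m3@params[[nm]][[fld]][ii] <- m3@params[[nm]][[fld]][ii] - h
          ana <- g[[nm]][[fld]][ii]
        }
        num <- (loss_fn(m2) - loss_fn(m3)) / (2 * h)
        expect_lt(abs(num - ana), 1e-4 * max(1, abs(num) + abs(ana)))
      }
    }
  }
})

test_that("checkpoints reload to bit-identical posterior-mean logits", {
  m <- buildDBayesNet(tiny_config(), input_length = 64, seed = 6,
                      classes = c("non-SLE", "SLE"))
  x <- matrix(rnorm(64 * 3), 64, 3)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(predictLogits(m, x), predictLogits(m2, x))
  expect_identical(m2@classes, m@classes)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadCheckpoint(bad), "checkpoint")
})
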