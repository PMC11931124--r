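test_that("subject-grouped splitting keeps replicates together, stratified", {
  set.seed(1)
  ss <- tiny_labeled_set(n_sub = 10L, reps = 3L)
  parts <- splitBySubject(ss, train_frac = 0.8, seed = 4)
  expect_equal(ncol(parts$train), 24L)
  expect_equal(ncol(parts$test), 6L)
  expect_length(intersect(unique(spectrumInfo(parts$train)$subject_id),
                          unique(spectrumInfo(parts$test)$subject_id)), 0L)
  # determinism under the seed
  parts2 <- splitBySubject(ss, train_frac = 0.8, seed = 4)
  expect_identical(colnames(parts$test), colnames(parts2$test))

  # stratification: 40 + 40 subjects, 50/50 -> 20 + 20 per side
  big <- tiny_labeled_set(n_sub = 80L, reps = 1L)
  p <- splitBySubject(big, train_frac = 0.5, seed = 9)
  tab <- table(classLabels(p$test))
  expect_equal(as.integer(tab), c(20L, 20L))

  expect_error(splitBySubject(SpectrumSet(1:3 * 100, matrix(0, 3, 2),
                                          label = c("A", "B"))),
               "at least 2")
})

test_that("the ELBO loss composes cross-entropy and scaled KL", {
  lg <- matrix(0, 4, 2)                    # uniform logits
  lab <- c(1L, 2L, 1L, 2L)
  expect_equal(elboLoss(lg, lab, kl = 99, beta = 0), log(2),
               tolerance = 1e-12)
  expect_equal(elboLoss(lg, lab, kl = 10, beta = 1, n_minibatches = 5),
               log(2) + 2, tolerance = 1e-12)
  # spot-check the CE term against manual softmax
  lg2 <- matrix(c(2, -1, 0.5, 0), 2, 2, byrow = TRUE)
  p1 <- exp(2) / (exp(2) + exp(-1))
  p2 <- exp(0) / (exp(0.5) + exp(0))
  expect_equal(elboLoss(lg2, c(1L, 2L), kl = 0),
               mean(-log(c(p1, p2))), tolerance = 1e-12)
})

test_that("training reduces the loss, is seeded, and lr 0 is a no-op", {
  ss <- tiny_labeled_set(n_sub = 8L, reps = 2L, P = 48L, seed = 3)
  m <- buildDBayesNet(tiny_config(), input_length = 48, seed = 1)
  cfg <- trainConfig(epochs = 8, batch_size = 8, seed = 5)
  r1 <- trainDBayesNet(m, ss, cfg)
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
  r2 <- trainDBayesNet(m, ss, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@params, r2$model@params)

  r0 <- trainDBayesNet(m, ss, trainConfig(epochs = 2, batch_size = 8,
                                          learning_rate = 0, seed = 5))
  expect_identical(r0$model@params, m@params)
  # with frozen parameters the KL is exactly flat (the CE still fluctuates
  # with the per-pass weight noise)
  expect_equal(diff(r0$history$kl), 0, tolerance = 1e-12)
})

test_that("Monte-Carlo prediction yields simplex probabilities + entropy", {
  ss <- tiny_labeled_set(n_sub = 4L, reps = 2L, P = 48L, seed = 13)
  m <- buildDBayesNet(tiny_config(), input_length = 48, seed = 2,
                      classes = c("A", "B"))
  pr <- mcPredict(m, ss, T = 5, seed = 3)
  psum <- pr$prob.A + pr$prob.B
  expect_lt(max(abs(psum - 1)), 1e-9)
  expect_true(all(pr$entropy >= 0 & pr$entropy <= log(2) + 1e-12))
  expect_true(all(as.character(pr$predicted) %in% c("A", "B")))
  # T = 1 equals a single seeded stochastic pass
  one <- mcPredict(m, ss, T = 1, seed = 11)
  lg <- predictLogits(m, ss, sample = TRUE, seed = 11)
  p <- exp(lg) / rowSums(exp(lg))
  expect_equal(one$prob.A, unname(p[, 1]), tolerance = 1e-12)
  expect_true(all(one$sd.A == 0))
  # posterior-mean mode and input validation
  pm <- mcPredict(m, ss, T = "mean")
  expect_identical(pm, mcPredict(m, ss, T = "mean"))
  expect_error(mcPredict(m, ss, T = 0), "T must be")
})

test_that("confusion tables count predicted rows against actual columns", {
  cm <- confusionCounts(truth = c("+", "+", "-", "-"),
                        predicted = c("+", "-", "+", "-"),
                        classes = c("-", "+"))
  b <- binaryCounts(cm, positive = "+")
  expect_equal(unname(b), c(1L, 1L, 1L, 1L))
  # all-correct leaves the off-diagonal empty
  cm2 <- confusionCounts(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)
  # 3-class one-vs-rest: TP of class k is the k-th diagonal entry
  tr <- c("x", "y", "z", "x", "y", "z")
  pd <- c("x", "y", "y", "z", "y", "z")
  cm3 <- confusionCounts(tr, pd, classes = c("x", "y", "z"))
  for (k in c("x", "y", "z")) {
    expect_equal(unname(binaryCounts(cm3, positive = k)["TP"]),
                 unname(cm3[k, k]))
  }
  expect_error(confusionCounts(c("a", "q"), c("a", "a"), classes = "a"),
               "outside")
})

test_that("the four diagnostic metrics follow their defining ratios", {
  m <- classificationMetrics(c(TP = 9, FP = 2, TN = 8, FN = 1))
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["precision"]), 9 / 11)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["accuracy"]), 0.85)
  perfect <- classificationMetrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_true(all(perfect == 1))
  # a zero denominator is undefined, never zero
  und <- classificationMetrics(c(TP = 0, FP = 2, TN = 8, FN = 0))
  expect_true(is.na(und["sensitivity"]))
  expect_false(is.na(und["specificity"]))
})

test_that("metrics agree with brute-force recounts on random tables", {
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(c("neg", "pos"), n, replace = TRUE)
    pred <- sample(c("neg", "pos"), n, replace = TRUE)
    cm <- confusionCounts(truth, pred, classes = c("neg", "pos"))
    m <- classificationMetrics(cm)
    tp <- sum(truth == "pos" & pred == "pos")
    fp <- sum(truth == "neg" & pred == "pos")
    tn <- sum(truth == "neg" & pred == "neg")
    fn <- sum(truth == "pos" & pred == "neg")
    ref <- c(if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             (tp + tn) / n)
    expect_equal(unname(m), ref)
  }
})

test_that("ROC/AUC matches the Mann-Whitney oracle and handles extremes", {
  # perfectly separated scores
  r <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  # inverted labels on the same scores
  r2 <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r2$auc, 0)
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(23)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- round(rnorm(n), 1)       # rounding forces ties
    got <- rocCurve(scores, pos)$auc
    expect_equal(got, auc_pairwise(scores, pos), tolerance = 1e-12)
  }

  # large balanced random scores hover at 1/2
  set.seed(29)
  n <- 1e4
  pos <- rep(c(TRUE, FALSE), n / 2)
  expect_lt(abs(rocCurve(runif(n), pos)$auc - 0.5), 0.02)
})

test_that("our AUC agrees with pROC on a shared example", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- sample(c(0, 1), 150, replace = TRUE)
  scores <- truth * 0.5 + rnorm(150)
  ours <- rocCurve(scores, truth == 1)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(truth, scores)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluateModel assembles a coherent report", {
  ss <- tiny_labeled_set(n_sub = 6L, reps = 2L, P = 48L, seed = 7)
  m <- buildDBayesNet(tiny_config(), input_length = 48, seed = 3,
                      classes = c("A", "B"))
  rep <- evaluateModel(m, ss, T = 4, seed = 5)
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@confusion), ncol(ss))
  mets <- rep@metrics[, c("sensitivity", "precision", "specificity",
                          "accuracy")]
  expect_true(all(is.na(as.matrix(mets)) | (mets >= 0 & mets <= 1)))
  expect_true(all(rep@auc >= 0 & rep@auc <= 1))

  # a constant classifier's accuracy equals the prevalence of its class
  m0 <- m
  hw <- m0@params[["head.W"]]
  hw$mu[] <- 0; hw$rho[] <- -20
  hb <- m0@params[["head.b"]]
  hb$mu[] <- c(5, -5); hb$rho[] <- -20
  m0@params[["head.W"]] <- hw
  m0@params[["head.b"]] <- hb
  rep0 <- evaluateModel(m0, ss, T = "mean")
  prevalence_A <- mean(classLabels(ss) == "A")
  acc <- rep0@metrics$accuracy[rep0@metrics$class == "B"]
  expect_equal(acc, prevalence_A)
})

test_that("3-class evaluation reports per-class and macro summaries", {
  set.seed(41)
  P <- 48L
  labs <- rep(c("mild", "moderate", "severe"), each = 4)
  ss <- SpectrumSet(seq(500, 2000, length.out = P),
                    matrix(rnorm(P * 12), P, 12),
                    subject_id = paste0("s", 1:12), label = labs)
  m <- buildDBayesNet(tiny_config(n_classes = 3), input_length = P,
                      seed = 4, classes = c("mild", "moderate", "severe"))
  rep <- evaluateModel(m, ss, T = 3, seed = 6)
  expect_setequal(rep@metrics$class, c("mild", "moderate", "severe", "macro"))
  expect_setequal(names(rep@auc), c("mild", "moderate", "severe", "macro"))
  expect_equal(unname(rep@auc["macro"]),
               mean(rep@auc[c("mild", "moderate", "severe")]))
})
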