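# Monte-Carlo prediction with predictive uncertainty, confusion-matrix
# metrics (sensitivity, precision, specificity, accuracy), ROC/AUC, and the
# assembled evaluation report.

#' Monte-Carlo prediction with uncertainty
#'
#' Averages the softmax output over `T` reparameterized weight draws. The
#' predictive entropy (in nats, in `[0, ln K]`) of the averaged
#' probabilities is the model's uncertainty signal; the per-class standard
#' deviation across draws separates out the weight-posterior
#' (epistemic) spread. `T = "mean"` uses the deterministic posterior-mean
#' weights instead of sampling.
#'
#' @param model A trained [DBayesNet-class].
#' @param x A [SpectrumSet-class] (or matrix/array, see [predictLogits()]).
#' @param T Number of MC draws (>= 1), or `"mean"`.
#' @param seed Seed making the draws reproducible.
#' @return A data.frame of class `"predictionResult"`: one row per
#'   spectrum with `prob.<class>` columns (each row sums to 1),
#'   `predicted`, `entropy`, and `sd.<class>` columns.
#' @export
mcPredict <- function(model, x, T = 30L, seed = NULL) {
  stopifnot(methods::is(model, "DBayesNet"))
  mean_mode <- identical(T, "mean")
  if (!mean_mode) {
    T <- as.integer(T)
    if (is.na(T) || T < 1) stop("T must be >= 1 (or \"mean\")")
  }
  xin <- as_input_array(x)
  B <- dim(xin)[3]
  K <- model@config$n_classes
  ids <- if (methods::is(x, "SpectrumSet")) colnames(x) else
    paste0("item", seq_len(B))
  probs <- with_seed(seed, {
    if (mean_mode) {
      p <- softmax_cols(nn_forward(model, xin, sample = FALSE,
                                   train = FALSE)$logits)
      array(p, dim = c(K, B, 1))
    } else {
      # each Monte-Carlo network = one weight draw + its own normalization
      # statistics, re-estimated on the stored calibration spectra (batch
      # statistics depend on the weights, so frozen training-time averages
      # would not match any individual draw)
      draws <- array(0, dim = c(K, B, T))
      for (t in seq_len(T)) {
        eps <- draw_eps(model@params)
        mdl <- model
        mdl@buffers <- recalibrate_buffers(model, eps)
        draws[, , t] <- softmax_cols(nn_forward(mdl, xin, sample = TRUE,
                                                train = FALSE,
                                                eps_list = eps)$logits)
      }
      draws
    }
  })
  pmean <- apply(probs, c(1, 2), mean)                    # K x B
  psd <- if (dim(probs)[3] > 1) apply(probs, c(1, 2), stats::sd)
         else matrix(0, K, B)
  ent <- apply(pmean, 2, entropy_nats)
  pred <- model@classes[max.col(t(pmean), ties.method = "first")]
  out <- data.frame(spectrum_id = ids, row.names = NULL)
  for (k in seq_len(K)) out[[paste0("prob.", model@classes[k])]] <- pmean[k, ]
  out$predicted <- factor(pred, levels = model@classes)
  out$entropy <- ent
  for (k in seq_len(K)) out[[paste0("sd.", model@classes[k])]] <- psd[k, ]
  class(out) <- c("predictionResult", "data.frame")
  out
}

#' Confusion matrix (rows = predicted, columns = actual)
#'
#' @param truth,predicted Factors or characters of equal length; levels must
#'   lie inside `classes`.
#' @param classes Class labels; default the union of levels, with the last
#'   level treated as positive in binary summaries.
#' @return A K x K integer table of class `"confusionMatrix"`, predicted in
#'   rows and actual in columns, with attribute `positive`.
#' @export
confusionCounts <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  classes <- classes %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(c(truth, predicted), classes)
  if (length(bad)) stop("labels outside the class set: ",
                        paste(unique(bad), collapse = ", "))
  tab <- table(factor(predicted, levels = classes),
               factor(truth, levels = classes))
  names(dimnames(tab)) <- c("predicted", "actual")
  structure(as.matrix(tab), class = "confusionMatrix",
            positive = classes[length(classes)])
}

#' Binary TP/FP/TN/FN reduction of a confusion matrix
#'
#' For a K-class table, the one-vs-rest reduction for `positive`: TP is the
#' diagonal entry of the positive class, FP the rest of its predicted row,
#' FN the rest of its actual column, TN everything else.
#'
#' @param cm A `"confusionMatrix"`.
#' @param positive Positive class (default: the table's `positive`
#'   attribute).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
binaryCounts <- function(cm, positive = NULL) {
  positive <- positive %||% attr(cm, "positive")
  stopifnot(positive %in% rownames(cm))
  i <- match(positive, rownames(cm))
  TP <- cm[i, i]
  FP <- sum(cm[i, -i])
  FN <- sum(cm[-i, i])
  TN <- sum(cm) - TP - FP - FN
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity
#' `TN/(TN+FP)` and accuracy `(TP+TN)/(TP+TN+FP+FN)`. A metric whose
#' denominator is zero is reported as `NA` ("undefined"), never as 0.
#'
#' @param cm A `"confusionMatrix"` (or named vector with TP, FP, TN, FN).
#' @param positive Positive class for the one-vs-rest reduction.
#' @return Named numeric vector
#'   `c(sensitivity, precision, specificity, accuracy)`.
#' @examples
#' classificationMetrics(c(TP = 9, FP = 2, TN = 8, FN = 1))
#' @export
classificationMetrics <- function(cm, positive = NULL) {
  b <- if (inherits(cm, "confusionMatrix")) binaryCounts(cm, positive)
       else cm[c("TP", "FP", "TN", "FN")]
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = rat(b["TP"], b["TP"] + b["FN"]),
    precision = rat(b["TP"], b["TP"] + b["FP"]),
    specificity = rat(b["TN"], b["TN"] + b["FP"]),
    accuracy = rat(b["TP"] + b["TN"], sum(b))) |>
    stats::setNames(c("sensitivity", "precision", "specificity", "accuracy"))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties included
#' simultaneously) and integrates the curve by the trapezoidal rule.
#'
#' @param scores Numeric positive-class scores.
#' @param truth Logical/factor truth; `positive` names the positive level.
#' @param positive Positive level of `truth` (default: `TRUE` for logicals,
#'   last level for factors).
#' @return A list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocCurve <- function(scores, truth, positive = NULL) {
  scores <- as.numeric(scores)
  if (is.logical(truth)) {
    pos <- truth
  } else {
    truth <- as.factor(truth)
    positive <- positive %||% levels(truth)[nlevels(truth)]
    pos <- truth == positive
  }
  P <- sum(pos); Ng <- sum(!pos)
  if (P == 0 || Ng == 0) stop("both classes must be present in truth")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / Ng, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Evaluation report
#'
#' Assembled by [evaluateModel()]: the confusion matrix, the four
#' diagnostic metrics (per class one-vs-rest plus macro average for
#' multi-class), ROC points and AUC (one-vs-rest macro AUC for
#' multi-class), and the per-spectrum prediction table.
#'
#' @slot confusion K x K matrix, predicted in rows.
#' @slot metrics Data.frame: one row per class plus `"macro"`.
#' @slot roc List of per-class ROC point data.frames.
#' @slot auc Named numeric (per class and `macro`).
#' @slot predictions The `"predictionResult"` data.frame.
#' @slot positive Positive class used for the headline binary metrics.
#' @export
setClass("EvalReport",
         representation(confusion = "matrix", metrics = "data.frame",
                        roc = "list", auc = "numeric",
                        predictions = "data.frame", positive = "character"))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport on", nrow(object@predictions), "spectra\n")
  cat("confusion (rows = predicted, cols = actual):\n")
  print(object@confusion)
  hm <- object@metrics[object@metrics$class == object@positive, ]
  cat(sprintf("positive class '%s': sens %.3f  prec %.3f  spec %.3f  acc %.3f  AUC %.3f\n",
              object@positive, hm$sensitivity, hm$precision, hm$specificity,
              hm$accuracy, object@auc[[object@positive]]))
  invisible(NULL)
})

#' Evaluate a trained model on a labeled test set
#'
#' Runs [mcPredict()], derives the confusion matrix, the four diagnostic
#' metrics and ROC/AUC per class (one-vs-rest), and assembles an
#' [EvalReport-class]. For the binary task the positive class is the last
#' class level.
#'
#' @param model A trained [DBayesNet-class].
#' @param test_set A labeled [SpectrumSet-class].
#' @param T MC draws (default 30) or `"mean"`.
#' @param seed Seed for the MC draws.
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(model, test_set, T = 30L, seed = NULL) {
  stopifnot(methods::is(model, "DBayesNet"),
            methods::is(test_set, "SpectrumSet"))
  truth <- factor(as.character(classLabels(test_set)),
                  levels = model@classes)
  if (anyNA(truth)) stop("test spectra must carry labels from the model's classes")
  pred <- mcPredict(model, test_set, T = T, seed = seed)
  cm <- confusionCounts(truth, pred$predicted, classes = model@classes)
  classes <- model@classes
  rows <- lapply(classes, function(cl) {
    data.frame(class = cl, t(classificationMetrics(cm, positive = cl)))
  })
  metrics <- do.call(rbind, rows)
  macro <- data.frame(class = "macro",
                      t(colMeans(metrics[, -1, drop = FALSE], na.rm = TRUE)))
  metrics <- rbind(metrics, macro)
  roc <- list(); auc <- numeric()
  for (cl in classes) {
    rc <- rocCurve(pred[[paste0("prob.", cl)]], truth == cl,
                   positive = NULL)
    roc[[cl]] <- rc$points
    auc[[cl]] <- rc$auc
  }
  auc[["macro"]] <- mean(auc[classes])
  methods::new("EvalReport", confusion = unclass(cm), metrics = metrics,
               roc = roc, auc = auc, predictions = as.data.frame(pred),
               positive = classes[length(classes)])
}

#' Headline metrics of a report as a named list
#' @param report An [EvalReport-class].
#' @export
reportSummary <- function(report) {
  stopifnot(methods::is(report, "EvalReport"))
  hm <- report@metrics[report@metrics$class == report@positive, ]
  list(accuracy = hm$accuracy, precision = hm$precision,
       sensitivity = hm$sensitivity, specificity = hm$specificity,
       auc = unname(report@auc[report@positive]),
       confusion = report@confusion)
}

#' Serialize an EvalReport to JSON
#' @param report An [EvalReport-class].
#' @param path Output file.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(methods::is(report, "EvalReport"))
  obj <- list(confusion = report@confusion, metrics = report@metrics,
              auc = as.list(report@auc), positive = report@positive,
              roc = report@roc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
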