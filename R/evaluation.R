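#' Fit the held-out evaluation classifier
#'
#' Training sets are scored by a probabilistic classifier deliberately
#' different from the committee learner, so that training-set quality is not
#' judged by the same model family that selected the samples. The default is
#' a gradient-boosted tree ensemble (logistic objective) producing
#' `P(minority)` scores in \[0, 1\]; it is deterministic under a fixed seed
#' and single-threaded fitting.
#'
#' @param x numeric feature matrix.
#' @param y integer labels (1 = minority, 0 = majority); both classes
#'   required.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosting hyper-parameters.
#' @return object of class `eval_scorer` with a `predict()` method returning
#'   minority-class probabilities.
#' @export
fit_eval_classifier <- function(x, y, seed = 1L, nrounds = 30, max_depth = 3,
                                eta = 0.3) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("evaluation classifier needs both classes in the training set",
         call. = FALSE)
  fit <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = nrounds,
    verbose = 0))
  structure(list(fit = fit, n_features = ncol(x), seed = as.integer(seed)),
            class = "eval_scorer")
}

#' @export
predict.eval_scorer <- function(object, newdata, ...) {
  if (inherits(newdata, "sample_pool")) newdata <- newdata$features
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
}

#' Hard classification at a threshold
#'
#' Maps a probabilistic score to a class label: 1 (minority) iff
#' `score > theta`, strictly, so a score exactly at the threshold is labeled
#' majority.
#'
#' @param score numeric scores in \[0, 1\] (vectorized).
#' @param theta decision threshold in \[0, 1\].
#' @return integer labels (1/0).
#' @export
hard_label <- function(score, theta) {
  stopifnot(is.numeric(score))
  check_number(theta, "theta", lower = 0, upper = 1)
  if (any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  as.integer(score > theta)
}

#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the ground truth.
#'
#' @param truth,predicted equal-length label vectors.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted) || !length(truth))
    stop("truth and predicted must have equal positive length", call. = FALSE)
  mean(truth == predicted)
}

#' ROC curve, AUC and operating point by threshold sweep
#'
#' Sweeps the decision threshold over all distinct score values plus 0 and 1,
#' computing the true- and false-positive rate at each (strict `>` rule, as
#' in [hard_label()]). The AUC is the trapezoidal area under the resulting
#' curve, which equals the Mann-Whitney pairwise-comparison statistic with
#' ties credited 1/2. The operating point is the threshold maximizing
#' Youden's J = TPR - FPR (ties broken toward the lower threshold); accuracy
#' is reported at that threshold.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param truth integer labels (1 = minority positive class, 0 = majority);
#'   both classes must be present.
#' @return object of class `eval_result`: list with `roc` (data.frame
#'   `theta`, `fpr`, `tpr`), `auc`, `theta` (operating point), `accuracy`
#'   (at the operating point) and `scores`.
#' @export
roc_and_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L)
    stop("AUC undefined: truth contains a single class", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  ths <- sort(unique(c(0, 1, scores)), decreasing = TRUE)
  pos <- truth == 1L
  tpr <- vapply(ths, function(th) mean(scores[pos] > th), numeric(1))
  fpr <- vapply(ths, function(th) mean(scores[!pos] > th), numeric(1))
  roc <- data.frame(theta = ths, fpr = fpr, tpr = tpr)
  # ensure the (1,1) endpoint (scores exactly 0 are never called positive)
  if (roc$tpr[nrow(roc)] < 1 || roc$fpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(theta = NA_real_, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  j <- roc$tpr - roc$fpr
  cand <- which(!is.na(roc$theta))
  best <- cand[j[cand] == max(j[cand])]
  theta_star <- min(roc$theta[best])              # ties -> lower threshold
  acc <- accuracy(truth, hard_label(scores, theta_star))
  structure(list(roc = roc, auc = auc, theta = theta_star, accuracy = acc,
                 scores = scores),
            class = "eval_result")
}

#' Evaluate a training set against a held-out test pool
#'
#' Fits the evaluation classifier on the labeled training set, scores the
#' test pool, and reports ROC/AUC and accuracy at the operating point.
#'
#' @param x,y labeled training features and labels.
#' @param test_pool a `sample_pool` with ground-truth labels.
#' @param seed integer seed for the evaluation classifier.
#' @param ... passed to [fit_eval_classifier()].
#' @return an `eval_result` (see [roc_and_auc()]).
#' @export
evaluate_training_set <- function(x, y, test_pool, seed = 1L, ...) {
  stopifnot(inherits(test_pool, "sample_pool"))
  scorer <- fit_eval_classifier(x, y, seed = seed, ...)
  roc_and_auc(predict(scorer, test_pool), test_pool$labels)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AUC = %.4f, accuracy = %.4f at theta* = %.4f\n",
              x$auc, x$accuracy, x$theta))
  invisible(x)
}

#' @export
plot.eval_result <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2, xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
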