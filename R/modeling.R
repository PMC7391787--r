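# Radial-basis SVM training and all evaluation machinery: grid search,
# confusion counts, Sn/Sp/Acc/MCC, jackknife (leave-one-out) and stratified
# k-fold cross-validation. Compositions already lie in [0, 1], so no feature
# scaling is applied anywhere.

#' SVM configuration
#'
#' @param cost Regularization parameter C (> 0).
#' @param gamma Radial-basis kernel width (> 0). This is the kernel parameter
#'   often written `g` in the SVM literature — unrelated to the dipeptide gap.
#' @return An `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = 1) {
  if (cost <= 0 || gamma <= 0) stop("cost and gamma must be > 0", call. = FALSE)
  structure(list(cost = cost, gamma = gamma, kernel = "radial"),
            class = "svm_config")
}

#' Train a radial-basis SVM
#'
#' C-classification SVM on a labeled feature matrix, labels in \{+1, -1\}.
#' Training is deterministic for fixed input. No scaling is applied.
#'
#' @param fm A `feature_matrix` with both classes present.
#' @param config An [svm_config()].
#' @return An `svm_handle` wrapping the fitted model with its feature names.
#' @export
svm_train <- function(fm, config = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$x) == 0L || nrow(fm$x) == 0L)
    stop("empty feature matrix", call. = FALSE)
  if (length(unique(fm$labels)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  fit <- e1071::svm(x = fm$x, y = factor(fm$labels, levels = c(-1L, 1L)),
                    type = "C-classification", kernel = "radial",
                    cost = config$cost, gamma = config$gamma, scale = FALSE)
  structure(list(fit = fit, features = colnames(fm$x), config = config),
            class = "svm_handle")
}

#' @export
predict.svm_handle <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(object$features))
    stop("feature dimension mismatch: model expects ",
         length(object$features), " features, got ", ncol(x), call. = FALSE)
  if (!is.null(colnames(x)) && !identical(colnames(x), object$features)) {
    if (!all(object$features %in% colnames(x)))
      stop("feature names do not match the trained model", call. = FALSE)
    x <- x[, object$features, drop = FALSE]
  }
  as.integer(as.character(stats::predict(object$fit, x)))
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every (cost, gamma) pair by stratified k-fold cross-validated
#' accuracy and returns the best configuration. Ties break deterministically:
#' highest accuracy, then smallest cost, then smallest gamma.
#'
#' The default grid is the standard coarse log2 lattice:
#' `C = 2^(-5), 2^(-3), ..., 2^15` and `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param fm A `feature_matrix`.
#' @param cost,gamma Numeric vectors of candidate values.
#' @param folds Number of CV folds.
#' @param seed Seed controlling fold assignment.
#' @return The winning [svm_config()], with the CV accuracy in attribute
#'   `"cv_accuracy"` and the full grid in attribute `"grid"`.
#' @export
grid_search <- function(fm, cost = 2^seq(-5, 15, by = 2),
                        gamma = 2^seq(-15, 3, by = 2),
                        folds = 5L, seed = 1L) {
  if (!length(cost) || !length(gamma)) stop("empty grid", call. = FALSE)
  grid <- expand.grid(cost = sort(cost), gamma = sort(gamma))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    kfold_accuracy(fm, svm_config(grid$cost[i], grid$gamma[i]), folds, seed)
  }, numeric(1))
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  out <- svm_config(best$cost, best$gamma)
  attr(out, "cv_accuracy") <- best$accuracy
  attr(out, "grid") <- grid
  out
}

#' Confusion counts for signed labels
#'
#' @param pred,truth Integer vectors over \{+1, -1\}, equal length.
#' @return A `confusion_counts`: list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  if (!all(c(pred, truth) %in% c(-1L, 1L)))
    stop("labels must be +1 or -1", call. = FALSE)
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 FP = sum(pred == 1L & truth == -1L),
                 FN = sum(pred == -1L & truth == 1L),
                 TN = sum(pred == -1L & truth == -1L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + FN + TN + FP)`,
#' `MCC = (TN * TP - FP * FN) / sqrt((TP+FP)(FN+TN)(TP+FN)(TN+FP))`.
#'
#' Degenerate denominators follow the usual conventions and are flagged
#' rather than raised: `Sn = 0` when no positives were evaluated, `Sp = 0`
#' when no negatives, `MCC = 0` when any factor of its denominator is 0. The
#' names of the affected metrics are recorded in attribute `"flags"`.
#'
#' @param counts A `confusion_counts` (or a list with TP/FP/FN/TN).
#' @return A `metrics_report`: list with `Sn`, `Sp`, `Acc`, `MCC`.
#' @examples
#' m <- classification_metrics(confusion(c(1, -1), c(1, -1)))
#' m$Acc  # 1
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  flags <- character(0)
  if (tp + fn == 0) { sn <- 0; flags <- c(flags, "Sn") } else sn <- tp / (tp + fn)
  if (tn + fp == 0) { sp <- 0; flags <- c(flags, "Sp") } else sp <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fn + tn + fp)
  den <- (tp + fp) * (fn + tn) * (tp + fn) * (tn + fp)
  if (den == 0) { mcc <- 0; flags <- c(flags, "MCC") }
  else mcc <- (tn * tp - fp * fn) / sqrt(den)
  structure(list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc),
            class = "metrics_report", flags = flags)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn = %.4f  Sp = %.4f  Acc = %.4f  MCC = %.4f\n",
              x$Sn, x$Sp, x$Acc, x$MCC))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  (degenerate, set by convention: ",
                      paste(fl, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation
#'
#' The most rigorous cross-validation: each sample is predicted by a model
#' trained on the remaining N - 1, and the N out-of-sample predictions are
#' aggregated into one confusion table. Deterministic — no fold randomness.
#'
#' @param fm A `feature_matrix` with >= 2 samples per class.
#' @param config An [svm_config()].
#' @return List with `counts` (`confusion_counts`), `metrics`
#'   (`metrics_report`) and `predictions`.
#' @export
jackknife_eval <- function(fm, config = svm_config()) {
  n <- nrow(fm$x)
  if (min(table(fm$labels)) < 2L)
    stop("jackknife needs >= 2 samples per class", call. = FALSE)
  preds <- vapply(seq_len(n), function(i) {
    train <- subset_samples(fm, -i)
    if (length(unique(train$labels)) < 2L)
      stop("training fold lost a class at sample ", i, call. = FALSE)
    predict(svm_train(train, config), fm$x[i, , drop = FALSE])
  }, integer(1))
  counts <- confusion(preds, fm$labels)
  list(counts = counts, metrics = classification_metrics(counts),
       predictions = preds)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin to folds, so every sample lands in exactly one fold.
make_folds <- function(labels, folds, seed) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > min(table(labels)))
    stop("folds exceeds the smallest class size", call. = FALSE)
  assign <- integer(length(labels))
  with_seed(as.integer(seed), {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validated accuracy
#'
#' @param fm A `feature_matrix`.
#' @param config An [svm_config()].
#' @param folds Number of folds (>= 2, at most the smallest class size).
#' @param seed Seed controlling fold assignment; the caller's RNG state is
#'   untouched.
#' @return Overall accuracy: the fraction of samples predicted correctly,
#'   each sample tested exactly once.
#' @export
kfold_accuracy <- function(fm, config = svm_config(), folds = 5L, seed = 1L) {
  assign <- make_folds(fm$labels, folds, seed)
  correct <- 0L
  for (f in seq_len(max(assign))) {
    test_i <- which(assign == f)
    model <- svm_train(subset_samples(fm, -test_i), config)
    preds <- predict(model, fm$x[test_i, , drop = FALSE])
    correct <- correct + sum(preds == fm$labels[test_i])
  }
  correct / nrow(fm$x)
}

#' Build an IFS accuracy evaluator
#'
#' Returns a closure suitable for [ifs_select()]'s `evaluator` argument:
#' stratified k-fold CV accuracy at a fixed SVM configuration (or jackknife
#' when `method = "jackknife"`).
#'
#' @param config An [svm_config()].
#' @param folds,seed Fold settings for the CV method.
#' @param method `"cv"` (default) or `"jackknife"`.
#' @return A function `feature_matrix -> accuracy`.
#' @export
make_cv_evaluator <- function(config = svm_config(), folds = 5L, seed = 1L,
                              method = c("cv", "jackknife")) {
  method <- match.arg(method)
  force(config); force(folds); force(seed)
  if (method == "cv") {
    function(fm) kfold_accuracy(fm, config, folds, seed)
  } else {
    function(fm) jackknife_eval(fm, config)$metrics$Acc
  }
}
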