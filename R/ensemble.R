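# The vote-stacking ensemble: per-encoding base SVMs (ten g-gap models for
# g = 0..9 plus five reduced-alphabet models), a sensitivity filter on the
# held-out test set, re-encoding of sequences as +/-1 vote vectors, and a
# final SVM trained on those votes. With the full pipeline the filter
# typically retains a handful of models (nine in the original study, hence
# 9-dimensional vote vectors), but any k >= 1 is handled.

#' Pipeline control settings
#'
#' Collects every tunable of the training pipeline. Defaults reproduce the
#' published settings where stated: gaps `g = 0..9`, the five built-in cluster
#' profiles at their optimal peptide orders, 80/20 stratified split upstream,
#' sensitivity threshold 0.20, ANOVA + IFS feature selection for the g-gap
#' models (the reduced-alphabet models keep their full feature set).
#'
#' @param gs Integer vector of gap sizes for g-gap base models.
#' @param profiles Character vector of cluster-profile names.
#' @param do_ifs Run ANOVA + IFS on g-gap models (`TRUE`) or keep all 400
#'   features (`FALSE`).
#' @param ifs_raac Also run ANOVA + IFS on the reduced-alphabet models.
#' @param ifs_k_grid Subset sizes for the IFS curve; `NULL` = every size.
#' @param cost,gamma Hyperparameter grid for [grid_search()].
#' @param folds CV folds for grid search and the IFS evaluator.
#' @param seed Master seed for fold assignment and stacking.
#' @param sensitivity_threshold Minimum test-set sensitivity a base model
#'   needs to enter the ensemble.
#' @param stacking `"out_of_fold"` — vote vectors for final-classifier
#'   training come from 5-fold cross-fitted base models (leakage-free
#'   default) — or `"resubstitution"` — frozen base models predict their own
#'   training data.
#' @return A `vote_control` list.
#' @export
vote_control <- function(gs = 0:9,
                         profiles = c("Op5", "Op8", "Op9", "Op11", "Op13"),
                         do_ifs = TRUE, ifs_raac = FALSE, ifs_k_grid = NULL,
                         cost = 2^seq(-5, 15, by = 2),
                         gamma = 2^seq(-15, 3, by = 2),
                         folds = 5L, seed = 42L,
                         sensitivity_threshold = 0.2,
                         stacking = c("out_of_fold", "resubstitution")) {
  structure(
    list(gs = as.integer(gs), profiles = profiles, do_ifs = do_ifs,
         ifs_raac = ifs_raac, ifs_k_grid = ifs_k_grid,
         cost = cost, gamma = gamma, folds = as.integer(folds),
         seed = as.integer(seed),
         sensitivity_threshold = sensitivity_threshold,
         stacking = match.arg(stacking)),
    class = "vote_control"
  )
}

# Fit one base model: encode, optionally rank + IFS-prune, grid-search the
# SVM, train on the training split, evaluate on the test split. The grid
# search runs once on the full feature set and its winner is reused along the
# IFS curve, keeping the procedure desk-scale.
fit_base_model <- function(split, spec, control, do_ifs) {
  train_fm <- encode_dataset(split$train, spec)
  test_fm <- encode_dataset(split$test, spec)
  config <- grid_search(train_fm, control$cost, control$gamma,
                        control$folds, control$seed)
  features <- colnames(train_fm$x)
  ifs <- NULL
  if (do_ifs) {
    ranking <- anova_f_scores(train_fm)
    evaluator <- make_cv_evaluator(config, control$folds, control$seed)
    ifs <- ifs_select(train_fm, ranking, evaluator, control$ifs_k_grid)
    features <- ifs$optimal_features
    train_fm <- subset_features(train_fm, features)
    test_fm <- subset_features(test_fm, features)
  }
  model <- svm_train(train_fm, config)
  preds <- predict(model, test_fm)
  counts <- confusion(preds, test_fm$labels)
  structure(
    list(name = encoder_label(spec), encoder = spec, features = features,
         config = config, model = model, ifs = ifs,
         test_metrics = classification_metrics(counts)),
    class = "base_model"
  )
}

#' @export
print.base_model <- function(x, ...) {
  cat("Base model ", x$name, ": ", length(x$features), " features, C = ",
      signif(x$config$cost, 3), ", gamma = ", signif(x$config$gamma, 3),
      "; test ", sep = "")
  print(x$test_metrics)
  invisible(x)
}

#' Train the per-encoding base models
#'
#' Builds one radial-basis SVM per encoder: a g-gap dipeptide model for every
#' gap in `control$gs` (each with ANOVA-F ranked, IFS-selected features by
#' default) and a reduced-alphabet n-peptide model for every profile in
#' `control$profiles` at its optimal order. Each model is trained on the
#' training split and its Sn/Sp/Acc/MCC measured on the test split. With the
#' defaults this yields the 15 models (10 g-gap + 5 reduced-alphabet) of the
#' full pipeline.
#'
#' @param split A `dataset_split` from [split_dataset()].
#' @param control A [vote_control()].
#' @return List of `base_model` objects, in construction order (g ascending,
#'   then profiles).
#' @export
train_base_models <- function(split, control = vote_control()) {
  stopifnot(inherits(split, "dataset_split"))
  specs <- c(lapply(control$gs, ggap_spec),
             lapply(control$profiles, function(p) raac_spec(p)))
  do_ifs <- c(rep(control$do_ifs, length(control$gs)),
              rep(control$ifs_raac, length(control$profiles)))
  mapply(function(spec, ifs) fit_base_model(split, spec, control, ifs),
         specs, do_ifs, SIMPLIFY = FALSE)
}

#' Filter base models by test-set sensitivity
#'
#' Keeps the models whose test sensitivity reaches `threshold` (0.20 by
#' default), preserving the original order; the removed models are reported
#' in attribute `"removed"`.
#'
#' @param models List of `base_model` objects with populated test metrics.
#' @param threshold Minimum sensitivity, in \[0, 1\].
#' @return The retained sub-list; error if nothing survives.
#' @export
filter_models <- function(models, threshold = 0.2) {
  sn <- vapply(models, function(m) m$test_metrics$Sn, numeric(1))
  keep <- sn >= threshold
  if (!any(keep))
    stop("all base models fall below sensitivity ", threshold,
         "; no ensemble possible", call. = FALSE)
  out <- models[keep]
  attr(out, "removed") <- vapply(models[!keep], `[[`, character(1), "name")
  out
}

#' Re-encode sequences as vote vectors
#'
#' Each retained base model casts a signed vote (+1/-1 predicted label) on
#' each sequence; the ordered votes form the input representation of the
#' final stacked classifier. With nine retained models this is the
#' 9-dimensional +/-1 vector of the original study.
#'
#' @param data A `labeled_dataset` (labels may be `NA` for pure prediction).
#' @param models Non-empty list of `base_model` objects, frozen.
#' @return A `feature_matrix` of votes, one column per model, values +/-1.
#' @export
vote_encode <- function(data, models) {
  if (!length(models)) stop("no base models", call. = FALSE)
  votes <- vapply(models, function(m) predict_base(m, data),
                  integer(nrow(data)))
  votes <- matrix(as.numeric(votes), nrow = nrow(data),
                  dimnames = list(data$id,
                                  vapply(models, `[[`, character(1), "name")))
  feature_matrix(votes, data$label, data$id)
}

# Predict labels for a dataset with one frozen base model.
predict_base <- function(model, data) {
  min_len <- encoder_min_length(model$encoder)
  too_short <- nchar(data$sequence) < min_len
  if (any(too_short))
    stop("record(s) too short for base model ", model$name, ": ",
         paste(data$id[too_short], collapse = ", "), call. = FALSE)
  fm <- encode_dataset(data, model$encoder)
  predict(model$model, subset_features(fm, model$features))
}

#' Train the vote-stacking ensemble
#'
#' Re-encodes the training split as vote vectors and trains the final
#' radial-basis SVM on them. Under the default `"out_of_fold"` stacking
#' policy each training sequence's votes come from base models re-fitted
#' without its fold (same encoder, features and hyperparameters), so the
#' final classifier never sees a vote produced by a model that was trained on
#' that sequence; `"resubstitution"` uses the frozen base models directly.
#' The deployed base models are frozen either way — cross-fitting only
#' generates the training votes.
#'
#' @param split The `dataset_split` the base models were trained on.
#' @param models Filtered list of `base_model` objects.
#' @param control The [vote_control()] used throughout.
#' @return A `vote_ensemble`: retained base models, the final classifier and
#'   its configuration, the threshold and stacking policy.
#' @export
train_vote_ensemble <- function(split, models, control = vote_control()) {
  if (!length(models)) stop("no base models", call. = FALSE)
  train <- split$train
  if (control$stacking == "resubstitution") {
    vote_fm <- vote_encode(train, models)
  } else {
    assign <- make_folds(train$label, control$folds, control$seed)
    votes <- matrix(NA_real_, nrow(train), length(models),
                    dimnames = list(train$id,
                                    vapply(models, `[[`, character(1), "name")))
    for (f in seq_len(max(assign))) {
      held <- which(assign == f)
      sub <- split_like(train, -held)
      held_data <- split_like(train, held)
      for (j in seq_along(models)) {
        m <- models[[j]]
        fm <- subset_features(encode_dataset(sub, m$encoder), m$features)
        refit <- svm_train(fm, m$config)
        hfm <- subset_features(encode_dataset(held_data, m$encoder), m$features)
        votes[held, j] <- predict(refit, hfm)
      }
    }
    vote_fm <- feature_matrix(votes, train$label, train$id)
  }
  if (nrow(unique(vote_fm$x)) == 1L)
    stop("degenerate vote matrix: every training sequence received the ",
         "identical vote vector (", paste(vote_fm$x[1, ], collapse = ","),
         "); the final classifier cannot separate the classes", call. = FALSE)
  final_config <- grid_search(vote_fm, control$cost, control$gamma,
                              control$folds, control$seed)
  final_model <- svm_train(vote_fm, final_config)
  structure(
    list(base_models = models, final_model = final_model,
         final_config = final_config,
         sensitivity_threshold = control$sensitivity_threshold,
         stacking = control$stacking, control = control),
    class = "vote_ensemble"
  )
}

# Row-subset a labeled_dataset.
split_like <- function(data, i) {
  labeled_dataset(data$id[i], data$sequence[i], data$label[i])
}

#' @export
print.vote_ensemble <- function(x, ...) {
  cat("Vote-stacking ensemble: ", length(x$base_models),
      " base models (", paste(vapply(x$base_models, `[[`, character(1), "name"),
                              collapse = ", "),
      "), stacking = ", x$stacking, "\n", sep = "")
  invisible(x)
}

#' Predict with a vote-stacking ensemble
#'
#' Each sequence is vote-encoded by the frozen base models and the final
#' classifier assigns the label. In `batch = "tolerant"` mode a sequence that
#' violates some base model's length precondition gets `NA` and the rest are
#' still predicted; `"strict"` aborts.
#'
#' @param object A `vote_ensemble`.
#' @param newdata A `labeled_dataset` (labels ignored) or character vector of
#'   sequences.
#' @param batch `"strict"` or `"tolerant"`.
#' @param ... Unused.
#' @return Integer vector over \{+1, -1\} (with `NA` entries in tolerant
#'   mode), input order preserved.
#' @export
predict.vote_ensemble <- function(object, newdata,
                                  batch = c("strict", "tolerant"), ...) {
  batch <- match.arg(batch)
  if (length(newdata) == 0L || (is.data.frame(newdata) && nrow(newdata) == 0L))
    return(integer(0))
  if (is.character(newdata)) {
    newdata <- labeled_dataset(paste0("q", seq_along(newdata)), newdata,
                               rep(NA_integer_, length(newdata)))
  }
  if (nrow(newdata) == 0L) return(integer(0))
  min_len <- max(vapply(object$base_models,
                        function(m) encoder_min_length(m$encoder), integer(1)))
  ok <- nchar(newdata$sequence) >= min_len
  if (!all(ok) && batch == "strict") {
    offender <- vapply(object$base_models, function(m)
      encoder_min_length(m$encoder), integer(1))
    worst <- object$base_models[[which.max(offender)]]$name
    stop("record(s) too short for base model ", worst, ": ",
         paste(newdata$id[!ok], collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_integer_, nrow(newdata))
  if (any(ok)) {
    sub <- split_like_na(newdata, which(ok))
    votes <- vote_encode(sub, object$base_models)
    out[ok] <- predict(object$final_model, votes)
  }
  out
}

# Row subset that tolerates NA labels.
split_like_na <- function(data, i) {
  out <- data.frame(id = data$id[i], sequence = data$sequence[i],
                    label = data$label[i], stringsAsFactors = FALSE)
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Evaluate an ensemble on a labeled dataset
#'
#' @param ensemble A `vote_ensemble`.
#' @param data A fully labeled `labeled_dataset`.
#' @return List with `counts` and `metrics`.
#' @export
evaluate_ensemble <- function(ensemble, data) {
  preds <- predict(ensemble, data)
  counts <- confusion(preds, data$label)
  list(counts = counts, metrics = classification_metrics(counts))
}

#' Train the full pipeline
#'
#' One call from labeled dataset to deployed ensemble: stratified split, base
#' models, sensitivity filter, vote stacking, test-set evaluation.
#'
#' @param data A `labeled_dataset`.
#' @param control A [vote_control()].
#' @param fraction Training fraction for the split.
#' @return List with `split`, `base_models` (all 15 under defaults),
#'   `retained` (the filtered list), `ensemble`, and `test` (counts +
#'   metrics of the ensemble on the held-out test split).
#' @export
train_pipeline <- function(data, control = vote_control(), fraction = 0.8) {
  split <- split_dataset(data, fraction, control$seed)
  base <- train_base_models(split, control)
  retained <- filter_models(base, control$sensitivity_threshold)
  ensemble <- train_vote_ensemble(split, retained, control)
  test <- evaluate_ensemble(ensemble, split$test)
  list(split = split, base_models = base, retained = retained,
       ensemble = ensemble, test = test)
}

#' Persist / restore a trained ensemble
#'
#' The ensemble directory holds the serialized models plus a JSON manifest
#' (model names, features, hyperparameters, threshold, stacking policy) so a
#' stored ensemble's provenance is readable without loading it.
#'
#' @param ensemble A `vote_ensemble`.
#' @param dir Directory to create/use.
#' @return `dir` (or the restored `vote_ensemble` for `load_ensemble`).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("antioxvote")),
    base_models = lapply(ensemble$base_models, function(m)
      list(name = m$name, n_features = length(m$features),
           cost = m$config$cost, gamma = m$config$gamma,
           test_Sn = m$test_metrics$Sn)),
    final = list(cost = ensemble$final_config$cost,
                 gamma = ensemble$final_config$gamma),
    sensitivity_threshold = ensemble$sensitivity_threshold,
    stacking = ensemble$stacking
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  path <- file.path(dir, "ensemble.rds")
  if (!file.exists(path)) stop("no ensemble found in ", dir, call. = FALSE)
  readRDS(path)
}
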