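# Small-scale pipeline settings shared by the ensemble tests: two g-gap
# models plus one reduced-alphabet model, a tiny hyperparameter grid, no IFS.
tiny_control <- function(seed = 1, threshold = 0.2, ...) {
  vote_control(gs = c(0, 1), profiles = "Op5", do_ifs = FALSE,
               cost = c(1, 32), gamma = c(2^-5, 2^-1), folds = 5,
               seed = seed, sensitivity_threshold = threshold, ...)
}

strong_data <- function(seed = 1, n = 50) {
  generate_synthetic(synth_config(n_pos = n, n_neg = n,
                                  length_range = c(40, 150), effect = 5,
                                  signal_channel = ggap_spec(1), seed = seed))
}

test_that("base-model training produces one tagged spec per encoder", {
  d <- strong_data(seed = 2, n = 30)
  split <- split_dataset(d, 0.8, seed = 2)
  models <- train_base_models(split, tiny_control(seed = 2))
  expect_length(models, 3)
  expect_equal(vapply(models, `[[`, character(1), "name"),
               c("g0", "g1", "Op5.n3"))
  for (m in models) {
    expect_s3_class(m, "base_model")
    expect_s3_class(m$test_metrics, "metrics_report")
    space <- antioxvote:::encoder_feature_names(m$encoder)
    expect_true(all(m$features %in% space))
    expect_true(length(m$features) >= 1)
  }
})

test_that("the model matching the planted signal beats a mismatched gap", {
  d <- strong_data(seed = 3, n = 50)  # signal at g = 1
  split <- split_dataset(d, 0.8, seed = 3)
  ctrl <- vote_control(gs = c(1, 9), profiles = character(0), do_ifs = FALSE,
                       cost = c(1, 32), gamma = c(2^-5, 2^-1), folds = 5,
                       seed = 3)
  models <- train_base_models(split, ctrl)
  acc <- vapply(models, function(m) m$test_metrics$Acc, numeric(1))
  expect_gt(acc[1], acc[2])   # g = 1 model strictly better than g = 9
})

test_that("the sensitivity filter keeps order and reports removals", {
  mk <- function(name, sn) structure(
    list(name = name, test_metrics = structure(list(Sn = sn),
                                               class = "metrics_report")),
    class = "base_model")
  models <- list(mk("m1", 0.1), mk("m2", 0.5), mk("m3", 0.19), mk("m4", 0.9))
  kept <- filter_models(models, 0.2)
  expect_equal(vapply(kept, `[[`, character(1), "name"), c("m2", "m4"))
  expect_equal(attr(kept, "removed"), c("m1", "m3"))
  expect_length(filter_models(models, 0), 4)
  zeroed <- lapply(models, function(m) { m$test_metrics$Sn <- 0; m })
  expect_error(filter_models(zeroed, 0.2), "no ensemble")
})

test_that("vote encoding yields one signed vote per retained model", {
  d <- strong_data(seed = 4, n = 30)
  split <- split_dataset(d, 0.8, seed = 4)
  models <- train_base_models(split, tiny_control(seed = 4))
  votes <- vote_encode(split$test, models)
  expect_equal(dim(votes$x), c(nrow(split$test), 3))
  expect_true(all(votes$x %in% c(-1, 1)))
  expect_equal(colnames(votes$x), c("g0", "g1", "Op5.n3"))
  votes2 <- vote_encode(split$test, models)
  expect_identical(votes$x, votes2$x)   # frozen models, stable votes
})

test_that("stacking trains, predicts, and round-trips through persistence", {
  d <- strong_data(seed = 5, n = 40)
  split <- split_dataset(d, 0.8, seed = 5)
  ctrl <- tiny_control(seed = 5, threshold = 0)
  models <- train_base_models(split, ctrl)
  ens <- train_vote_ensemble(split, models, ctrl)
  expect_s3_class(ens, "vote_ensemble")
  expect_length(ens$base_models, 3)

  preds <- predict(ens, split$test)
  expect_length(preds, nrow(split$test))
  expect_true(all(preds %in% c(-1L, 1L)))
  expect_identical(predict(ens, split$test), preds)
  expect_equal(predict(ens, character(0)), integer(0))

  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_identical(predict(back, split$test), preds)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man$base_models, 3)

  res <- evaluate_ensemble(ens, split$test)
  expect_s3_class(res$metrics, "metrics_report")
})

test_that("resubstitution stacking is available and distinct from out-of-fold", {
  d <- strong_data(seed = 6, n = 40)
  split <- split_dataset(d, 0.8, seed = 6)
  ctrl_oof <- tiny_control(seed = 6, threshold = 0)
  ctrl_res <- tiny_control(seed = 6, threshold = 0,
                           stacking = "resubstitution")
  models <- train_base_models(split, ctrl_oof)
  e1 <- train_vote_ensemble(split, models, ctrl_oof)
  e2 <- train_vote_ensemble(split, models, ctrl_res)
  expect_equal(e1$stacking, "out_of_fold")
  expect_equal(e2$stacking, "resubstitution")
  expect_length(predict(e2, split$test), nrow(split$test))
})

test_that("length preconditions propagate with the offending model named", {
  d <- strong_data(seed = 7, n = 30)
  split <- split_dataset(d, 0.8, seed = 7)
  ctrl <- vote_control(gs = 9, profiles = character(0), do_ifs = FALSE,
                       cost = 1, gamma = 2^-3, folds = 5, seed = 7,
                       sensitivity_threshold = 0)
  models <- train_base_models(split, ctrl)
  ens <- train_vote_ensemble(split, models, ctrl)
  shorty <- labeled_dataset("tiny", "ACDEF", NA_integer_)
  expect_error(predict(ens, shorty), "g9.*tiny")
  # tolerant batch mode: short record NA, valid record still predicted
  mixed <- labeled_dataset(c("tiny", "ok"),
                           c("ACDEF", strong_data(seed = 8, n = 1)$sequence[1]),
                           c(NA_integer_, NA_integer_))
  out <- predict(ens, mixed, batch = "tolerant")
  expect_true(is.na(out[1]))
  expect_true(out[2] %in% c(-1L, 1L))
})

test_that("single-model stacking degenerates to a pass-through of its votes", {
  d <- strong_data(seed = 9, n = 40)
  split <- split_dataset(d, 0.8, seed = 9)
  ctrl <- vote_control(gs = 1, profiles = character(0), do_ifs = FALSE,
                       cost = c(1, 32), gamma = c(2^-5, 2^-1), folds = 5,
                       seed = 9, sensitivity_threshold = 0)
  models <- train_base_models(split, ctrl)
  ens <- train_vote_ensemble(split, models, ctrl)
  base_votes <- vote_encode(split$test, models)$x[, 1]
  stacked <- predict(ens, split$test)
  # 1-D vote space: the stack can only copy or invert the base model
  agree <- mean(stacked == base_votes)
  expect_true(agree == 1 || agree == 0)
})
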