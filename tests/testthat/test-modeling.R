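test_that("SVM training predicts separable data and enforces contracts", {
  fm <- make_blobs(10, d = 2, seed = 1)
  model <- svm_train(fm, svm_config(10, 0.5))
  expect_equal(predict(model, fm), fm$labels)   # interpolation on separable data
  expect_error(predict(model, matrix(0, 1, 5)), "dimension mismatch")
  expect_error(svm_train(feature_matrix(matrix(numeric(0), 0, 0), integer(0))),
               "empty")
  one_class <- feature_matrix(matrix(rnorm(10), 5, 2), rep(1L, 5))
  expect_error(svm_train(one_class), "both classes")
})

test_that("a 1-D threshold toy agrees with an independent SVM implementation", {
  x <- matrix(c(0, 0.05, 0.1, 0.9, 0.95, 1), dimnames = list(NULL, "f"))
  y <- c(-1L, -1L, -1L, 1L, 1L, 1L)
  fm <- feature_matrix(x, y)
  model <- svm_train(fm, svm_config(100, 1))
  probe <- matrix(c(0.95, 0.02), dimnames = list(NULL, "f"))
  expect_equal(predict(model, probe), c(1L, -1L))

  skip_if_not_installed("kernlab")
  ref <- kernlab::ksvm(x, factor(y), type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = 1), C = 100, scaled = FALSE)
  ref_pred <- as.integer(as.character(kernlab::predict(ref, probe)))
  expect_equal(predict(model, probe), ref_pred)
})

test_that("grid search returns the best configuration deterministically", {
  fm <- make_blobs(8, d = 2, seed = 2)
  single <- grid_search(fm, cost = 4, gamma = 0.25, folds = 4, seed = 1)
  expect_equal(single$cost, 4)
  expect_equal(single$gamma, 0.25)

  best <- grid_search(fm, cost = c(1, 10), gamma = c(0.1, 1), folds = 4,
                      seed = 1)
  expect_equal(attr(best, "cv_accuracy"), 1)   # separable blobs
  best2 <- grid_search(fm, cost = c(1, 10), gamma = c(0.1, 1), folds = 4,
                       seed = 1)
  expect_identical(unclass(best)[c("cost", "gamma")],
                   unclass(best2)[c("cost", "gamma")])
  # all-tie grid: smallest cost then smallest gamma
  expect_equal(best$cost, 1)
  expect_equal(best$gamma, 0.1)
})

test_that("confusion counts match hand tallies and validate input", {
  c1 <- confusion(c(1, -1), c(1, -1))
  expect_equal(unclass(c1)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  c2 <- confusion(c(-1, 1), c(1, -1))
  expect_equal(c2$TP + c2$TN, 0L)
  c3 <- confusion(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(unclass(c3)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_error(confusion(1, c(1, -1)), "equal length")
  expect_error(confusion(0, 1), "\\+1 or -1")
})

test_that("metrics follow their definitions and degenerate conventions", {
  perfect <- classification_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unclass(perfect), list(Sn = 1, Sp = 1, Acc = 1, MCC = 1),
               ignore_attr = TRUE)

  onlypos <- classification_metrics(list(TP = 5, FN = 5, TN = 0, FP = 0))
  expect_equal(onlypos$Sn, 0.5)
  expect_equal(onlypos$MCC, 0)
  expect_true(all(c("Sp", "MCC") %in% attr(onlypos, "flags")))

  m <- classification_metrics(list(TP = 60, FP = 10, FN = 40, TN = 90))
  expect_equal(m$Acc, 0.75)
  expect_equal(m$MCC, 5000 / sqrt(70 * 130 * 100 * 100))
  expect_equal(m$MCC, 0.524, tolerance = 1e-3)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(13)
  for (i in 1:50) {
    cnt <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
                FN = sample(0:30, 1), TN = sample(0:30, 1))
    if (sum(unlist(cnt)) == 0) next
    m <- classification_metrics(cnt)
    expect_true(m$Sn >= 0 && m$Sn <= 1)
    expect_true(m$Sp >= 0 && m$Sp <= 1)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
    P <- cnt$TP + cnt$FN; N <- cnt$TN + cnt$FP
    if (P > 0 && N > 0) {
      expect_equal(m$Acc, (m$Sn * P + m$Sp * N) / (P + N))
      # swapping the label convention swaps Sn/Sp and keeps |MCC|
      sw <- classification_metrics(list(TP = cnt$TN, TN = cnt$TP,
                                        FP = cnt$FN, FN = cnt$FP))
      expect_equal(sw$Sn, m$Sp)
      expect_equal(sw$Sp, m$Sn)
      expect_equal(abs(sw$MCC), abs(m$MCC))
    }
  }
})

test_that("jackknife makes one held-out prediction per sample", {
  fm <- make_blobs(10, d = 2, seed = 3)
  res <- jackknife_eval(fm, svm_config(10, 0.5))
  expect_length(res$predictions, nrow(fm$x))
  expect_equal(with(res$counts, TP + FP + FN + TN), nrow(fm$x))
  expect_equal(res$metrics$Acc, 1)   # fully separable blobs

  noise <- make_noise_fm(20, d = 4, seed = 8)
  acc <- jackknife_eval(noise, svm_config(1, 0.25))$metrics$Acc
  expect_gte(acc, 0.3)               # 3 binomial sigma around 0.5, n = 40
  expect_lte(acc, 0.7)

  tiny <- feature_matrix(matrix(rnorm(6), 3, 2), c(1L, 1L, -1L))
  expect_error(jackknife_eval(tiny), ">= 2 samples")
})

test_that("k-fold accuracy partitions samples once and is seeded", {
  fm <- make_blobs(10, d = 2, seed = 4)
  expect_equal(kfold_accuracy(fm, svm_config(10, 0.5), 5, 1), 1)
  noise <- make_noise_fm(10, d = 3, seed = 9)
  a1 <- kfold_accuracy(noise, svm_config(1, 1), 5, 7)
  a2 <- kfold_accuracy(noise, svm_config(1, 1), 5, 7)
  expect_identical(a1, a2)
  expect_error(kfold_accuracy(fm, folds = 50), "smallest class")
  expect_error(kfold_accuracy(fm, folds = 1), ">= 2")
})

test_that("fold assignment is stratified and exhaustive", {
  labels <- rep(c(1L, -1L), c(20, 30))
  assign <- antioxvote:::make_folds(labels, 5, 3)
  expect_length(assign, 50)
  expect_true(all(assign %in% 1:5))
  for (f in 1:5) {
    expect_equal(sum(assign == f & labels == 1L), 4)
    expect_equal(sum(assign == f & labels == -1L), 6)
  }
})
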