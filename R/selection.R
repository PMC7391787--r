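# Univariate feature ranking by one-way ANOVA F-value and incremental
# feature selection (IFS): features are added from highest to lowest F, a
# classifier is evaluated at every subset size, and the subset at the
# accuracy peak is kept.

#' ANOVA F-value feature ranking
#'
#' For each feature, the one-way two-group F statistic
#' `F = MSB / MSW` with `MSB = sum_c n_c (m_c - m)^2 / (K - 1)` and
#' `MSW = sum_c sum_i (x_ic - m_c)^2 / (N - K)`, `K = 2`. Large F means the
#' feature's between-class variance dominates its within-class variance. For
#' two groups F equals the square of the pooled-variance t statistic.
#'
#' Degenerate cases: a feature constant everywhere gets `F = 0`; a feature
#' constant within each class but differing between classes gets `F = Inf`
#' and ranks above all finite values. Ties are broken by feature name.
#'
#' @param fm A `feature_matrix` with both classes present (>= 2 samples each).
#' @return An `fscore_ranking`: data.frame with columns `feature`, `f_value`,
#'   sorted by decreasing F.
#' @examples
#' fm <- feature_matrix(matrix(c(0, 1, 2, 3), 4, 1,
#'                             dimnames = list(NULL, "f1")),
#'                      c(1, 1, -1, -1))
#' anova_f_scores(fm)$f_value  # 8
#' @export
anova_f_scores <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  pos <- fm$x[y == 1L, , drop = FALSE]
  neg <- fm$x[y == -1L, , drop = FALSE]
  n1 <- nrow(pos); n2 <- nrow(neg)
  if (n1 < 2L || n2 < 2L)
    stop("both classes need >= 2 samples for an F ranking", call. = FALSE)
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  msb <- (n1 * (m1 - m)^2 + n2 * (m2 - m)^2)  # / (K - 1) with K = 2
  ssw <- colSums((pos - rep(m1, each = n1))^2) +
         colSums((neg - rep(m2, each = n2))^2)
  msw <- ssw / (n1 + n2 - 2L)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  ord <- order(-f, colnames(fm$x))
  structure(
    data.frame(feature = colnames(fm$x)[ord], f_value = as.numeric(f[ord]),
               stringsAsFactors = FALSE),
    class = c("fscore_ranking", "data.frame")
  )
}

#' Incremental feature selection
#'
#' Walks the F-ranked feature list: for each size `k` it keeps the top-`k`
#' features, asks `evaluator` for an accuracy, and records the point. The
#' optimum is the smallest `k` attaining the maximum accuracy (parsimony at
#' ties).
#'
#' @param fm A `feature_matrix`.
#' @param ranking An `fscore_ranking` covering `fm`'s features (computed with
#'   [anova_f_scores()] if omitted).
#' @param evaluator Function `feature_matrix -> accuracy in [0, 1]`, e.g. from
#'   [make_cv_evaluator()].
#' @param k_grid Subset sizes to evaluate; defaults to `1:D` (one point per
#'   possible size).
#' @return An `ifs_result`: list with `curve` (data.frame `k`, `accuracy`),
#'   `optimal_k`, `optimal_features`, `optimal_accuracy`.
#' @export
ifs_select <- function(fm, ranking = NULL, evaluator, k_grid = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), is.function(evaluator))
  if (is.null(ranking)) ranking <- anova_f_scores(fm)
  if (!setequal(ranking$feature, colnames(fm$x)))
    stop("ranking does not cover the matrix's features", call. = FALSE)
  D <- ncol(fm$x)
  if (is.null(k_grid)) k_grid <- seq_len(D)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L | k_grid > D)) stop("k_grid out of range", call. = FALSE)
  acc <- vapply(k_grid, function(k) {
    a <- tryCatch(
      evaluator(subset_features(fm, ranking$feature[seq_len(k)])),
      error = function(e) stop("IFS evaluator failed at k = ", k, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!is.finite(a) || a < 0 || a > 1)
      stop("IFS evaluator returned a non-accuracy at k = ", k, call. = FALSE)
    a
  }, numeric(1))
  best <- max(acc)
  opt_k <- k_grid[which(acc == best)[1L]]
  structure(
    list(curve = data.frame(k = k_grid, accuracy = acc),
         optimal_k = opt_k,
         optimal_features = ranking$feature[seq_len(opt_k)],
         optimal_accuracy = best),
    class = "ifs_result"
  )
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS: ", nrow(x$curve), " subset sizes evaluated; peak accuracy ",
      round(x$optimal_accuracy, 4), " at k = ", x$optimal_k, "\n", sep = "")
  invisible(x)
}

#' Write an IFS curve as TSV
#'
#' @param res An `ifs_result`.
#' @param path Output path (columns `k`, `accuracy`).
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(res, path) {
  utils::write.table(res$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
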