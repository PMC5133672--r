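#' Train an SVM classifier with stratified cross-validation
#'
#' Standardizes the training table (storing the transform for reuse on test
#' data), estimates accuracy by seeded stratified k-fold cross-validation
#' (fraction of points classified correctly), and refits the final model on
#' all data. Multiclass problems use one-vs-one voting. The regularization
#' constant is fixed at 1; the Gaussian kernel width is set by the median
#' heuristic on pairwise distances.
#'
#' @param table Feature table (data frame) or numeric matrix.
#' @param labels Class labels, each class with at least `folds` members.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param features Optional subset of feature columns to train on.
#' @return Object of class `classifier_bundle`: `transform`
#'   (`standardized_table`), `model` (the fitted [e1071::svm()]), `kernel`,
#'   `gamma`, `classes`, `features`, `cv_accuracy`, `folds`, `seed`.
#' @export
train_svm <- function(table, labels, kernel = c("linear", "gaussian"),
                      folds = 5L, seed = 1L, features = NULL) {
  kernel <- match.arg(kernel)
  x <- feature_matrix(table, features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  if (any(base::table(y) < folds))
    stopf("every class needs at least %d members for %d-fold CV",
          folds, folds)
  st <- standardize(x)
  z <- st$values
  gamma <- if (kernel == "gaussian") median_heuristic_gamma(z, seed) else
    1 / ncol(z)
  fold_id <- stratified_folds(y, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- svm_fit(z[tr, , drop = FALSE], y[tr], kernel, gamma)
    pred <- stats::predict(fit, z[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  model <- svm_fit(z, y, kernel, gamma)
  structure(list(transform = st, model = model, kernel = kernel,
                 gamma = gamma, classes = levels(y),
                 features = st$features,
                 cv_accuracy = correct / length(y),
                 folds = folds, seed = as.integer(seed)),
            class = "classifier_bundle")
}

svm_fit <- function(z, y, kernel, gamma) {
  e1071::svm(z, y, scale = FALSE, cost = 1,
             kernel = if (kernel == "gaussian") "radial" else "linear",
             gamma = gamma, probability = FALSE)
}

# Median heuristic: gamma = 1 / (2 * median(pairwise distance)^2), on a
# subsample for large n.
median_heuristic_gamma <- function(z, seed = 1L, max_n = 1000L) {
  if (nrow(z) > max_n)
    z <- z[withr::with_seed(as.integer(seed),
                            sample.int(nrow(z), max_n)), , drop = FALSE]
  med <- stats::median(stats::dist(z))
  if (med <= 0) return(1 / ncol(z))
  1 / (2 * med^2)
}

stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

# Internal: stratified CV accuracy on a bare matrix (used by RFE).
svm_cv_accuracy <- function(x, labels, kernel = "linear", folds = 5L,
                            seed = 1L) {
  b <- train_svm(x, labels, kernel = kernel, folds = folds, seed = seed)
  b$cv_accuracy
}

#' Classify new data with a trained bundle
#'
#' @param bundle A `classifier_bundle`.
#' @param table Feature table containing the bundle's features.
#' @return Factor of predicted classes.
#' @export
classify <- function(bundle, table) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  z <- apply_standardize(bundle$transform, table)
  if (inherits(bundle, "classifier_bundle_json"))
    predict_from_json_bundle(bundle, z)
  else
    stats::predict(bundle$model, z)
}

#' Per-class composition predicted for a sample
#'
#' Classifies every row of the table and reports the fraction of rows
#' assigned to each class (the predicted mixing ratio of a spiked sample).
#'
#' @param bundle A `classifier_bundle`.
#' @param table Feature table (>= 1 row).
#' @return Named numeric vector of per-class fractions summing to 1.
#' @export
predict_fractions <- function(bundle, table) {
  if (nrow(table) == 0L) stopf("cannot predict fractions of an empty table")
  pred <- classify(bundle, table)
  counts <- base::table(factor(pred, levels = bundle$classes))
  fr <- as.numeric(counts) / sum(counts)
  names(fr) <- bundle$classes
  fr
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values (ties
#' grouped at one threshold) and reports the true-positive rate
#' (sensitivity) against the false-positive rate (1 - specificity). The
#' area under the curve is computed by the trapezoid rule, which equals the
#' tie-corrected Mann--Whitney U statistic divided by n1*n2.
#'
#' @param scores Numeric scores, larger meaning more positive-like.
#' @param labels Binary labels; `positive` names the positive class.
#' @param positive Value of `labels` treated as positive (default: the
#'   larger of the two sorted unique values).
#' @return Object of class `roc_curve`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stopf("roc requires both classes present")
  if (is.null(positive)) positive <- lv[2L]
  pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_end <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  n1 <- sum(pos); n2 <- sum(!pos)
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n2)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[grp_end]), auc = auc),
            class = "roc_curve")
}
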