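#' Hierarchical backward feature elimination
#'
#' Greedy worst-first elimination: at every step each remaining feature is
#' tentatively removed, the criterion is recomputed on the reduced feature
#' set, and the removal giving the best criterion value is committed. In
#' `"clustering"` mode the criterion is the within/between
#' [clustering_error()] of a freshly fitted two-component [emgm()] on the
#' reduced data (the feature whose removal yields the lowest clustering
#' error goes first); in `"svm"` mode it is the 5-fold cross-validated
#' misclassification rate of an SVM refit on the reduced data. Ties are
#' resolved in `"svm"` mode by the classic SVM-RFE ranking -- among tied
#' candidates, the feature with the smallest squared weight in the linear
#' decision function is removed (on strongly separable data many removals
#' leave the CV error at zero, and the margin weights then carry the
#' ranking) -- and everywhere else by the lowest feature index.
#'
#' @param X Numeric matrix or feature table (standardized recommended).
#' @param labels Class labels (used directly in `"svm"` mode; in
#'   `"clustering"` mode the EMGM hard labels are scored and `labels` only
#'   sets the number of expected classes).
#' @param metric `"clustering_error"` or `"svm_cv_error"`.
#' @param floor Stop when this many features remain (>= 1).
#' @param seed Seed for k-means initializations / CV folds.
#' @param kernel SVM kernel for `"svm_cv_error"` mode.
#' @return Object of class `feature_ranking`: `elimination_order`
#'   (worst-first), `surviving` (the `floor` features retained last),
#'   `trajectory` (data frame of `n_features`, `metric` after each committed
#'   state, starting from the full set), `mode`.
#' @export
backward_eliminate <- function(X, labels,
                               metric = c("clustering_error", "svm_cv_error"),
                               floor = 1L, seed = 1L, kernel = "linear") {
  metric <- match.arg(metric)
  x <- feature_matrix(X)
  p <- ncol(x)
  if (p < 2L) stopf("need at least 2 features")
  if (floor < 1L || floor >= p) stopf("floor must be in [1, p - 1]")
  score <- function(cols) {
    xs <- x[, cols, drop = FALSE]
    if (metric == "clustering_error") {
      sol <- emgm(xs, k = 2L, seed = seed)
      clustering_error(xs, sol$labels)
    } else {
      1 - svm_cv_accuracy(xs, labels, kernel = kernel, folds = 5L,
                          seed = seed)
    }
  }
  remaining <- colnames(x)
  order_out <- character(0)
  traj <- data.frame(n_features = p, metric = score(remaining))
  while (length(remaining) > floor) {
    vals <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      vals[i] <- tryCatch(score(remaining[-i]), error = function(e) {
        warnf("subset without %s skipped: %s", remaining[i],
              conditionMessage(e))
        NA_real_
      })
    }
    if (all(is.na(vals))) stopf("criterion failed on every candidate subset")
    tied <- which(vals == min(vals, na.rm = TRUE))
    drop_i <- if (length(tied) > 1L && metric == "svm_cv_error") {
      w2 <- svm_feature_weights(x[, remaining, drop = FALSE], labels)
      tied[which.min(w2[tied])]         # residual ties: lowest index
    } else tied[1L]
    order_out <- c(order_out, remaining[drop_i])
    remaining <- remaining[-drop_i]
    traj <- rbind(traj, data.frame(n_features = length(remaining),
                                   metric = vals[drop_i]))
  }
  structure(list(elimination_order = c(order_out, remaining),
                 surviving = remaining,
                 trajectory = traj,
                 mode = if (metric == "clustering_error") "clustering"
                        else "svm"),
            class = "feature_ranking")
}

# Per-feature squared weights of a linear SVM, summed over one-vs-one class
# pairs: the SVM-RFE ranking score.
svm_feature_weights <- function(x, labels) {
  z <- standardize(x)$values
  y <- factor(labels)
  m <- e1071::svm(z, y, scale = FALSE, cost = 1, kernel = "linear")
  k <- nlevels(y)
  nsv <- m$nSV
  start <- cumsum(c(0L, nsv))
  w2 <- rep(0, ncol(z))
  names(w2) <- colnames(z)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    si <- (start[i] + 1L):start[i + 1L]
    sj <- (start[j] + 1L):start[j + 1L]
    w <- colSums(m$coefs[si, j - 1L] * m$SV[si, , drop = FALSE]) +
      colSums(m$coefs[sj, i] * m$SV[sj, , drop = FALSE])
    w2 <- w2 + w^2
  }
  w2
}
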