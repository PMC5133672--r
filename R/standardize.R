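#' Z-score a feature table and keep the transform
#'
#' Centres and scales each feature to sample mean 0 and SD 1, recording the
#' training statistics so held-out data can be standardized with the same
#' transform (never with its own moments). Zero-variance features are
#' excluded with a warning and flagged.
#'
#' @param table Data frame or matrix of numeric features (non-numeric
#'   columns such as `event_id` / `label` are dropped from the values but
#'   reported in `dropped_columns`).
#' @return Object of class `standardized_table`: `values` (n x p matrix),
#'   `center`, `scale`, `features`, `excluded` (zero-variance features).
#' @export
standardize <- function(table) {
  x <- feature_matrix(table)
  if (nrow(x) < 2L) stopf("standardize needs at least 2 rows")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  zero <- scale < .Machine$double.eps^0.5
  if (any(zero))
    warnf("excluding zero-variance feature(s): %s",
          paste(colnames(x)[zero], collapse = ", "))
  keep <- !zero
  structure(list(values = sweep(sweep(x[, keep, drop = FALSE], 2L,
                                      center[keep]), 2L, scale[keep], `/`),
                 center = center[keep], scale = scale[keep],
                 features = colnames(x)[keep],
                 excluded = colnames(x)[zero]),
            class = "standardized_table")
}

#' Apply a stored standardization transform to new data
#'
#' @param st A `standardized_table` (the training transform).
#' @param table New feature table containing at least `st$features`.
#' @return Matrix of the new rows in the training z-score coordinates.
#' @export
apply_standardize <- function(st, table) {
  stopifnot(inherits(st, "standardized_table"))
  x <- feature_matrix(table)
  missing <- setdiff(st$features, colnames(x))
  if (length(missing))
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  sweep(sweep(x[, st$features, drop = FALSE], 2L, st$center), 2L,
        st$scale, `/`)
}

# Numeric feature matrix from a feature table; drops id/label columns.
feature_matrix <- function(table, features = NULL) {
  if (is.matrix(table)) {
    x <- table
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  } else {
    num <- vapply(table, is.numeric, NA)
    num[names(num) %in% c("event_id", "label")] <- FALSE
    x <- as.matrix(table[, num, drop = FALSE])
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  x
}
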