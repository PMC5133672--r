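#' Pairwise-distance similarity matrix
#'
#' Euclidean distances between every pair of rows of a (standardized)
#' feature matrix. When labels are supplied, rows are ordered by class and
#' then original order, so that well-separated classes appear as blocks of
#' small within-class distances.
#'
#' @param X Numeric matrix or feature table (n >= 2).
#' @param labels Optional class labels used only for row ordering.
#' @return Symmetric n x n matrix with zero diagonal; the row ordering is
#'   attached as attribute `order`.
#' @export
similarity_matrix <- function(X, labels = NULL) {
  x <- feature_matrix(X)
  if (nrow(x) < 2L) stopf("need at least 2 rows")
  ord <- if (is.null(labels)) seq_len(nrow(x)) else order(labels)
  m <- as.matrix(stats::dist(x[ord, , drop = FALSE]))
  dimnames(m) <- NULL
  attr(m, "order") <- ord
  m
}

#' Principal component projection
#'
#' PCA of an already-standardized matrix. Loadings are orthonormal with the
#' sign convention that each component's largest-magnitude loading entry is
#' positive; explained variances are non-increasing.
#'
#' @param X Standardized numeric matrix (n > p).
#' @param n_components Number of components to return (<= p).
#' @return List with `scores` (n x k), `loadings` (p x k),
#'   `explained_variance`, `explained_fraction`.
#' @export
pca_project <- function(X, n_components = 2L) {
  x <- feature_matrix(X)
  if (nrow(x) <= ncol(x)) stopf("PCA here requires n > p")
  if (n_components > ncol(x)) stopf("n_components exceeds feature count")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- x %*% load
  ev <- pc$sdev^2
  list(scores = scores, loadings = load,
       explained_variance = ev[seq_len(n_components)],
       explained_fraction = (ev / sum(ev))[seq_len(n_components)])
}

#' Linear discriminant projection
#'
#' Directions maximizing the ratio of between-class to within-class scatter,
#' from the generalized eigenproblem `Sb v = lambda Sw v`; a ridge of 1e-6
#' is added to the within-class scatter when it is singular. At most
#' `n_classes - 1` discriminants exist.
#'
#' @param X Numeric matrix or feature table.
#' @param labels Class labels (>= 2 classes).
#' @param n_components Number of discriminants (<= classes - 1).
#' @return List with `scores`, `directions` (unit columns), `eigenvalues`.
#' @export
lda_project <- function(X, labels, n_components = NULL) {
  x <- feature_matrix(X)
  y <- factor(labels)
  k <- nlevels(y)
  if (k < 2L) stopf("LDA requires at least 2 classes")
  max_comp <- k - 1L
  if (is.null(n_components)) n_components <- min(max_comp, 2L)
  if (n_components > max_comp)
    stopf("at most %d discriminant(s) exist for %d classes", max_comp, k)
  p <- ncol(x)
  gm <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    rows <- x[y == cl, , drop = FALSE]
    m <- colMeans(rows)
    Sw <- Sw + crossprod(sweep(rows, 2L, m))
    Sb <- Sb + nrow(rows) * tcrossprod(m - gm)
  }
  if (min(eigen(Sw, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    Sw <- Sw + diag(1e-6, p)
  eg <- eigen(solve(Sw, Sb))
  keep <- seq_len(n_components)
  dirs <- Re(eg$vectors[, keep, drop = FALSE])
  dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), `/`)
  list(scores = x %*% dirs, directions = dirs,
       eigenvalues = Re(eg$values)[keep])
}

#' Median deformability-to-size ratio
#'
#' The population median of the per-cell ratio `D3 / A` -- a simple scalar
#' summary of relative cell stiffness that compensates for the
#' size-dependence of the applied hydrodynamic stress. Rows with
#' nonpositive `A` are excluded with a warning.
#'
#' @param table Feature table with columns `A` and `D3`.
#' @return Scalar median of D3/A (1/micrometre).
#' @export
deformability_size_ratio <- function(table) {
  a <- gate_column(table, "A")
  d3 <- gate_column(table, "D3")
  bad <- !(a > 0)
  if (any(bad)) {
    warnf("excluding %d row(s) with nonpositive A", sum(bad))
    a <- a[!bad]; d3 <- d3[!bad]
  }
  if (!length(a)) stopf("no rows with positive A")
  stats::median(d3 / a)
}
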