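#' Expectation-maximization for a Gaussian mixture (EMGM)
#'
#' Fits a k-component Gaussian mixture with full covariances by EM,
#' initialized from a seeded k-means partition. The E step computes
#' responsibilities in log space; the M step re-estimates weights, means and
#' covariances (maximum-likelihood, 1/n scaling) with a ridge of 1e-6 added
#' to each covariance diagonal for numerical stability. Iteration stops when
#' the relative log-likelihood improvement drops below `tol`; the
#' log-likelihood trace is non-decreasing by construction of EM.
#'
#' @param X Numeric matrix (n x p), typically standardized.
#' @param k Number of components (>= 1); requires `n > k * (p + 1)`.
#' @param seed Seed for the k-means initialization.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations; non-convergence returns the best
#'   solution with `converged = FALSE` and a warning.
#' @param ridge Diagonal covariance regularization.
#' @return Object of class `cluster_solution`: `k`, `weights`, `means`
#'   (k x p), `covariances` (p x p x k), `responsibilities` (n x k),
#'   `labels` (hard assignments), `loglik_trace`, `converged`.
#' @export
emgm <- function(X, k, seed = 1L, tol = 1e-6, max_iter = 500L,
                 ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 1L) stopf("k must be >= 1")
  if (n <= k * (p + 1)) stopf("too few rows (n = %d) for k = %d, p = %d",
                              n, k, p)
  init <- withr::with_seed(as.integer(seed), {
    if (k == 1L) rep(1L, n) else
      stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)$cluster
  })
  w <- tabulate(init, k) / n
  mu <- matrix(0, k, p)
  sig <- array(0, c(p, p, k))
  for (j in seq_len(k)) {
    rows <- X[init == j, , drop = FALSE]
    mu[j, ] <- colMeans(rows)
    cc <- crossprod(sweep(rows, 2L, mu[j, ])) / nrow(rows)
    sig[, , j] <- cc + diag(ridge, p)
  }
  loglik <- -Inf; trace <- numeric(0)
  resp <- matrix(0, n, k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step: log densities per component
    logd <- vapply(seq_len(k), function(j)
      dmvnorm_log(X, mu[j, ], sig[, , j]) + log(w[j]),
      numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_loglik <- sum(lse)
    resp <- exp(logd - lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(loglik) + 1e-12)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stopf("a mixture component collapsed to zero weight")
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      xc <- sweep(X, 2L, mu[j, ])
      sig[, , j] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(ridge, p)
    }
  }
  if (!converged) warnf("EM did not converge in %d iterations", max_iter)
  structure(list(k = k, weights = w, means = mu, covariances = sig,
                 responsibilities = resp,
                 labels = max.col(resp, ties.method = "first"),
                 loglik_trace = trace, converged = converged),
            class = "cluster_solution")
}

# Multivariate normal log-density via Cholesky.
dmvnorm_log <- function(X, mean, sigma) {
  p <- length(mean)
  ch <- chol(sigma)
  xc <- sweep(X, 2L, mean)
  z <- forwardsolve(t(ch), t(xc))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Within/between clustering-error statistic
#'
#' For a two-class labelling of points \eqn{x}, the clustering error is the
#' within-class scatter over the between-class scatter:
#' \deqn{E = \frac{\sum_{x_i \in C_1} \|x_i - m_{C_1}\|^2 +
#'                \sum_{x_j \in C_2} \|x_j - m_{C_2}\|^2}
#'               {n \, \|m_{C_1} - m_{C_2}\|^2}}
#' where \eqn{m_{C_1}, m_{C_2}} are the class means. Lower is better; the
#' statistic is invariant to global scaling and rigid rotation of the data,
#' and independent of sample size for a fixed population geometry.
#'
#' @param X Numeric matrix (n x p).
#' @param labels Vector with exactly two distinct values, both present.
#' @return Nonnegative scalar; `Inf` when the class means coincide.
#' @export
clustering_error <- function(X, labels) {
  X <- as.matrix(X)
  lv <- unique(labels)
  if (length(lv) != 2L) stopf("clustering_error requires exactly 2 classes")
  i1 <- labels == lv[1L]; i2 <- labels == lv[2L]
  if (!any(i1) || !any(i2)) stopf("both classes must be nonempty")
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  between <- sum((m1 - m2)^2)
  if (between < .Machine$double.eps) return(Inf)
  within <- sum(sweep(X[i1, , drop = FALSE], 2L, m1)^2) +
    sum(sweep(X[i2, , drop = FALSE], 2L, m2)^2)
  within / (nrow(X) * between)
}
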