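# Shared fixtures, built in code at test time.

# Fast noise-free render spec used throughout the extraction tests.
quiet_render <- function(...) {
  render_spec(psf_sigma = 0.8, noise_sd = 0, ...)
}

# Dense analytic polygon of an axis-aligned ellipse (optionally rotated).
ellipse_polygon <- function(a, b, n = 720L, angle = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1L] + x * cos(angle) - y * sin(angle),
        center[2L] + x * sin(angle) + y * cos(angle))
}

# Two canonical populations with strong (A, D3)-axis separation.
separated_specs <- function(n = 300L, seed = 1L) {
  list(defcyto:::canonical_population("c1", A = 14, D3 = 2.0, sd_A = 1,
                                      sd_D3 = 0.15, n = n, seed = seed),
       defcyto:::canonical_population("c2", A = 18, D3 = 1.3, sd_A = 1,
                                      sd_D3 = 0.15, n = n, seed = seed + 1L))
}

# n x 15 synthetic matrix with 3 informative features (class separation
# `sep` in SD units) and 12 pure-noise features; returns X and labels.
informative_noise_data <- function(n_per_class = 100L, sep = 4, seed = 1L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    X <- matrix(rnorm(n * 15L), n, 15L)
    colnames(X) <- paste0("f", seq_len(15L))
    labels <- rep(c(1L, 2L), each = n_per_class)
    X[labels == 2L, 1:3] <- X[labels == 2L, 1:3] + sep
    list(X = X, labels = labels)
  })
}

# Independent brute-force implementation of the clustering-error formula,
# written as a literal double loop over points.
clustering_error_bruteforce <- function(X, labels) {
  lv <- unique(labels)
  m1 <- colMeans(X[labels == lv[1L], , drop = FALSE])
  m2 <- colMeans(X[labels == lv[2L], , drop = FALSE])
  within <- 0
  for (i in seq_len(nrow(X))) {
    m <- if (labels[i] == lv[1L]) m1 else m2
    within <- within + sum((X[i, ] - m)^2)
  }
  within / (nrow(X) * sum((m1 - m2)^2))
}

# Tie-corrected Mann-Whitney AUC oracle: mean over all (pos, neg) pairs of
# 1/0.5/0 for win/tie/loss.
mann_whitney_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
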