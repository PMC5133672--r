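test_that("standardization zeroes means, units SDs and stores the transform", {
  withr::with_seed(2, {
    tab <- as.data.frame(matrix(rnorm(200 * 4, mean = 5, sd = 3), 200L))
    names(tab) <- c("A", "D3", "T1", "S1")
    st <- standardize(tab)
    expect_true(all(abs(colMeans(st$values)) < 1e-9))
    expect_true(all(abs(apply(st$values, 2L, sd) - 1) < 1e-9))
    # held-out data standardized with the training transform, not its own
    test <- as.data.frame(matrix(rnorm(50 * 4, mean = 9), 50L))
    names(test) <- names(tab)
    z <- apply_standardize(st, test)
    own <- scale(as.matrix(test))
    expect_equal(z, sweep(sweep(as.matrix(test), 2L, st$center), 2L,
                          st$scale, `/`))
    expect_gt(max(abs(z - own)), 0.1)
    # constant columns are flagged and excluded
    tab$C1 <- 1
    expect_warning(st2 <- standardize(tab), "zero-variance")
    expect_identical(st2$excluded, "C1")
    expect_false("C1" %in% st2$features)
  })
})

test_that("emgm with k = 1 reduces to the closed-form Gaussian fit", {
  withr::with_seed(3, {
    X <- matrix(rnorm(500 * 3), 500L)
    sol <- emgm(X, k = 1L, seed = 1L)
    expect_equal(as.numeric(sol$means), colMeans(X), tolerance = 1e-8)
    mle_cov <- crossprod(sweep(X, 2L, colMeans(X))) / nrow(X)
    expect_equal(sol$covariances[, , 1L] - diag(1e-6, 3L), mle_cov,
                 tolerance = 1e-8)
    expect_equal(sol$weights, 1)
  })
})

test_that("emgm separates well-separated clusters and is monotone in loglik", {
  withr::with_seed(4, {
    n <- 1000L
    X <- rbind(matrix(rnorm(n * 2), ncol = 2L),
               matrix(rnorm(n * 2, mean = 10), ncol = 2L))
    truth <- rep(1:2, each = n)
    sol <- emgm(X, k = 2L, seed = 9L)
    expect_gte(defcyto:::match_label_agreement(sol$labels, truth), 0.99)
    expect_true(all(diff(sol$loglik_trace) >= -1e-7))
    expect_equal(sum(sol$weights), 1, tolerance = 1e-12)
    expect_true(all(abs(rowSums(sol$responsibilities) - 1) < 1e-12))
    # component means within 3 standard errors of the true means
    for (m in list(c(0, 0), c(10, 10))) {
      i <- which.min(rowSums(sweep(sol$means, 2L, m)^2))
      expect_true(all(abs(sol$means[i, ] - m) < 3 / sqrt(n)))
    }
  })
  expect_error(emgm(matrix(rnorm(10), 5L), k = 3L), "too few rows")
})

test_that("emgm agrees with an independent mixture fitter on easy data", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves it in the caller frame
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(300 * 2, sd = 0.7), ncol = 2L),
               matrix(rnorm(300 * 2, mean = 5, sd = 0.7), ncol = 2L))
    sol <- emgm(X, k = 2L, seed = 1L)
    mc <- mclust::Mclust(X, G = 2L, modelNames = "VVV", verbose = FALSE)
    expect_gte(defcyto:::match_label_agreement(sol$labels,
                                               mc$classification), 0.995)
    ours <- sol$means[order(sol$means[, 1L]), ]
    theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1L]), ]
    expect_equal(ours, theirs, tolerance = 0.02, ignore_attr = TRUE)
  })
})

test_that("clustering error matches its brute-force oracle and invariances", {
  withr::with_seed(5, {
    X <- matrix(rnorm(400 * 5), 400L)
    labels <- rep(1:2, each = 200L)
    X[labels == 2L, 1L] <- X[labels == 2L, 1L] + 3
    e <- clustering_error(X, labels)
    expect_equal(e, clustering_error_bruteforce(X, labels),
                 tolerance = 1e-10)
    # scale invariance
    expect_equal(clustering_error(X * 7.3, labels), e, tolerance = 1e-12)
    # rotation invariance
    q <- qr.Q(qr(matrix(rnorm(25), 5L)))
    expect_equal(clustering_error(X %*% q, labels), e, tolerance = 1e-10)
    # zero within-class scatter
    Xp <- rbind(matrix(1, 10L, 2L), matrix(5, 10L, 2L))
    expect_equal(clustering_error(Xp, rep(1:2, each = 10L)), 0)
    # coincident means -> infinite-error signal
    expect_identical(clustering_error(Xp, rep(1:2, times = 10L)), Inf)
    expect_error(clustering_error(X, rep(1L, 400L)), "2 classes")
    # strictly decreasing in class-mean separation
    errs <- vapply(c(1, 2, 4, 8), function(d) {
      Y <- X; Y[labels == 2L, 1L] <- rnorm(200L) + d
      clustering_error(Y, labels)
    }, 0)
    expect_true(all(diff(errs) < 0))
  })
})

test_that("backward elimination retains informative features in both modes", {
  hits_cl <- 0L; hits_svm <- 0L
  for (seed in 1:10) {
    d <- informative_noise_data(n_per_class = 100L, sep = 4, seed = seed)
    r1 <- backward_eliminate(d$X, d$labels, "clustering_error", floor = 3L,
                             seed = seed)
    if (setequal(r1$surviving, c("f1", "f2", "f3"))) hits_cl <- hits_cl + 1L
    r2 <- backward_eliminate(d$X, d$labels, "svm_cv_error", floor = 3L,
                             seed = seed)
    if (setequal(r2$surviving, c("f1", "f2", "f3"))) hits_svm <- hits_svm + 1L
  }
  expect_gte(hits_cl, 9L)
  expect_gte(hits_svm, 9L)
})

test_that("elimination trajectories behave on minimal and informative data", {
  d <- informative_noise_data(n_per_class = 100L, sep = 4, seed = 1L)
  r <- backward_eliminate(d$X, d$labels, "clustering_error", floor = 2L,
                          seed = 1L)
  expect_identical(sort(r$elimination_order), sort(colnames(d$X)))
  expect_equal(nrow(r$trajectory), 14L)   # full set + one row per removal
  # removing pure-noise features lowers the within/between error: the
  # trajectory improves from the full set down to the informative floor
  expect_lt(r$trajectory$metric[nrow(r$trajectory)],
            r$trajectory$metric[1L])
  expect_true(all(diff(r$trajectory$metric[1:12]) <= 1e-9))
  # p = 2: a single comparison decides the order
  X2 <- d$X[, c("f1", "f4")]
  r2 <- backward_eliminate(X2, d$labels, "clustering_error", floor = 1L,
                           seed = 1L)
  expect_identical(r2$surviving, "f1")
})
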