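test_that("SVM achieves near-perfect CV accuracy on separable classes", {
  specs <- separated_specs(n = 250L, seed = 2L)
  tr <- do.call(rbind, lapply(specs, generate_feature_population))
  for (k in c("linear", "gaussian")) {
    b <- train_svm(tr, tr$label, kernel = k, seed = 5L)
    expect_gte(b$cv_accuracy, 0.99)
    expect_identical(b$classes, c("c1", "c2"))
  }
  few <- c(1:3, 251:253)
  expect_error(train_svm(tr[few, ], tr$label[few]), "at least 5 members")
})

test_that("permuted labels drive CV accuracy to chance", {
  withr::with_seed(6, {
    X <- matrix(rnorm(2000 * 5), 2000L)
    colnames(X) <- paste0("f", 1:5)
    y <- sample(rep(c("a", "b"), each = 1000L))
    b <- train_svm(X, y, kernel = "linear", seed = 1L)
    expect_lt(abs(b$cv_accuracy - 0.5), 0.03)
  })
})

test_that("duplicated features leave the CV accuracy within CV noise", {
  d <- informative_noise_data(n_per_class = 100L, sep = 3, seed = 4L)
  X1 <- d$X[, 1:3]
  X2 <- cbind(X1, X1); colnames(X2) <- paste0("g", 1:6)
  a1 <- train_svm(X1, d$labels, kernel = "linear", seed = 2L)$cv_accuracy
  a2 <- train_svm(X2, d$labels, kernel = "linear", seed = 2L)$cv_accuracy
  expect_lt(abs(a1 - a2), 0.03)
})

test_that("CV folds are stratified and seeded", {
  y <- factor(rep(c("a", "b"), times = c(60L, 40L)))
  f1 <- defcyto:::stratified_folds(y, 5L, seed = 3L)
  f2 <- defcyto:::stratified_folds(y, 5L, seed = 3L)
  expect_identical(f1, f2)
  for (fold in 1:5) {
    expect_equal(sum(f1 == fold & y == "a"), 12L)
    expect_equal(sum(f1 == fold & y == "b"), 8L)
  }
})

test_that("ROC handles perfect, null and tied scores; AUC = Mann-Whitney", {
  perfect <- roc(c(1, 2, 3, 11, 12, 13), rep(0:1, each = 3L))
  expect_equal(perfect$auc, 1)
  withr::with_seed(8, {
    null <- roc(rnorm(5000), rep(0:1, 2500L))
    expect_lt(abs(null$auc - 0.5), 0.02)
    # tie-corrected Mann-Whitney oracle on discretized (heavily tied) scores
    for (rep in 1:10) {
      n <- sample(50:200, 1L)
      scores <- sample(1:7, n, replace = TRUE)   # k tied groups
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2L) next
      got <- roc(scores, labels, positive = 1L)$auc
      expect_equal(got, mann_whitney_auc(scores, labels, 1L),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc(1:5, rep(1L, 5L)), "both classes")
})

test_that("ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    scores <- c(rnorm(150), rnorm(150, 1.2))
    labels <- rep(0:1, each = 150L)
    ours <- roc(scores, labels)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-10)
  })
})

test_that("predicted fractions are exact on separable mixtures", {
  specs <- separated_specs(n = 250L, seed = 3L)
  tr <- do.call(rbind, lapply(specs, generate_feature_population))
  b <- train_svm(tr, tr$label, kernel = "gaussian", seed = 7L)
  pure <- generate_spiked_mixture(specs, c(1, 0), 300L, seed = 11L)
  fr_pure <- predict_fractions(b, pure)
  expect_gte(fr_pure[["c1"]], 0.98)
  half <- generate_spiked_mixture(specs, c(0.5, 0.5), 400L, seed = 12L)
  fr_half <- predict_fractions(b, half)
  expect_lt(abs(fr_half[["c1"]] - 0.5), 0.02)
  expect_equal(sum(fr_half), 1)
  expect_error(predict_fractions(b, tr[0L, ]), "empty")
})

test_that("spike response recovers exact and noisy linear responses", {
  s <- c(0, 0.25, 0.5, 0.75, 1)
  ident <- spike_response(s, s)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  aff <- spike_response(s, 0.5 * s + 0.1)
  expect_equal(aff$slope, 0.5, tolerance = 1e-12)
  expect_equal(aff$intercept, 0.1, tolerance = 1e-12)
  # closed-form normal-equation oracle on noisy data
  withr::with_seed(10, {
    p <- s + rnorm(5L, 0, 0.02)
    got <- spike_response(s, p)
    beta <- sum((s - mean(s)) * (p - mean(p))) / sum((s - mean(s))^2)
    expect_equal(got$slope, beta, tolerance = 1e-10)
    expect_equal(got$intercept, mean(p) - beta * mean(s), tolerance = 1e-10)
  })
  expect_error(spike_response(c(0, 1), c(0, 1)), "3 distinct")
})

test_that("limit of detection is sd_max over slope", {
  expect_equal(limit_of_detection(1, 0.007), 0.007)
  expect_equal(limit_of_detection(2, 0.007), limit_of_detection(1, 0.007) / 2)
  expect_error(limit_of_detection(0, 0.01), "positive")
  # replicate-set recomputation: 3 sets x 5 ratios
  withr::with_seed(12, {
    s <- c(0, 0.25, 0.5, 0.75, 1)
    pred <- t(replicate(3L, s + rnorm(5L, 0, 0.01)))
    got <- spike_experiment(s, pred)
    sd_max <- max(apply(pred, 2L, sd))
    beta <- stats::coef(stats::lm(colMeans(pred) ~ s))[[2L]]
    expect_equal(got$lod, sd_max / beta, tolerance = 1e-12)
  })
})

test_that("classifier JSON round trip predicts identically (multiclass)", {
  specs <- separated_specs(n = 100L, seed = 5L)
  third <- defcyto:::canonical_population("c3", A = 22, D3 = 1.1,
                                          sd_A = 1, sd_D3 = 0.1,
                                          n = 100L, seed = 9L)
  tr <- do.call(rbind, lapply(c(specs, list(third)),
                              generate_feature_population))
  for (k in c("linear", "gaussian")) {
    b <- train_svm(tr, tr$label, kernel = k, seed = 13L)
    f <- withr::local_tempfile(fileext = ".json")
    write_classifier(b, f)
    b2 <- read_classifier(f)
    expect_identical(as.character(classify(b2, tr)),
                     as.character(classify(b, tr)))
    expect_equal(b2$cv_accuracy, b$cv_accuracy)
  }
})
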