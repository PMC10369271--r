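test_that("BPNN reaches 100% on linearly separable classes, deterministically", {
  d <- separable_features(n_per_class = 15, seed = 41)
  fit <- bpnn_train(d$features, d$labels, epochs = 300, seed = 41)
  pred <- bpnn_predict(fit, d$features)
  expect_equal(mean(pred$labels == d$labels), 1)
  expect_true(all(diff(fit$loss[c(1, 150, 300)]) < 0))  # loss decreases

  # identical seed -> bitwise-identical weights
  fit2 <- bpnn_train(d$features, d$labels, epochs = 300, seed = 41)
  expect_identical(fit$W1, fit2$W1)
  expect_identical(fit$W2, fit2$W2)
  expect_identical(fit$loss, fit2$loss)

  expect_error(bpnn_train(d$features[d$labels != 2, ], d$labels[d$labels != 2]),
               "three classes")
  bad <- d$features; bad[1, 1] <- NA
  expect_error(bpnn_train(bad, d$labels), "finite")
})

test_that("shuffled labels give near-chance held-out accuracy", {
  d <- separable_features(n_per_class = 20, seed = 43)
  set.seed(43)
  y_perm <- sample(d$labels)
  fold <- stratified_folds(y_perm, 5, seed = 43)
  test <- fold == 1
  fit <- bpnn_train(d$features[!test, ], y_perm[!test], epochs = 300, seed = 43)
  acc <- mean(bpnn_predict(fit, d$features[test, ])$labels == y_perm[test])
  expect_gte(acc, 1 / 3 - 0.15)
  expect_lte(acc, 1 / 3 + 0.15)
})

test_that("prediction produces proper probabilities and matches a hand-computed forward pass", {
  d <- separable_features(n_per_class = 10, seed = 47)
  fit <- bpnn_train(d$features, d$labels, epochs = 50, seed = 47)
  pred <- bpnn_predict(fit, d$features)
  expect_equal(rowSums(pred$prob), rep(1, nrow(d$features)), tolerance = 1e-12)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))

  # duplicating a row leaves its prediction unchanged
  two <- d$features[c(1, 1), ]
  p2 <- bpnn_predict(fit, two)
  expect_identical(p2$labels[1], p2$labels[2])

  # manual forward pass on one sample, written out in scalar arithmetic
  x <- d$features[5, ]
  xs <- (x - fit$scaler$mean) / fit$scaler$sd
  h <- 1 / (1 + exp(-(as.numeric(xs %*% fit$W1) + fit$b1)))
  z <- as.numeric(h %*% fit$W2) + fit$b2
  p_manual <- exp(z - max(z)) / sum(exp(z - max(z)))
  expect_equal(as.numeric(pred$prob[5, ]), p_manual, tolerance = 1e-12)

  expect_error(bpnn_predict(fit, d$features[, 1:5]), "9 feature")
})

test_that("stratified folds partition the data and preserve class balance", {
  d <- separable_features(n_per_class = 17, seed = 53)  # 51 samples
  folds <- 10
  fold <- stratified_folds(d$labels, folds, seed = 53)
  expect_setequal(unique(fold), 1:folds)
  sizes <- tabulate(fold, folds)
  expect_lte(max(sizes) - min(sizes), 1)
  overall <- table(d$labels) / length(d$labels)
  for (f in 1:folds) {
    inside <- table(factor(d$labels[fold == f], levels = 0:2))
    expected <- overall * sum(fold == f)
    expect_true(all(abs(inside - expected) <= 1))
  }
  # union of test folds is the whole dataset, pairwise disjoint by construction
  expect_equal(sort(unlist(lapply(1:folds, function(f) which(fold == f)))),
               seq_along(d$labels))
})

test_that("cross-validation picks a high-accuracy grid point on separable data", {
  d <- separable_features(n_per_class = 20, seed = 59)
  grid <- expand.grid(hidden = c(4, 6), lr = c(0.05, 0.1))
  res <- cross_validate(d$features, d$labels, folds = 5, hyper_grid = grid,
                        epochs = 400, seed = 59)
  expect_gte(res$cv_accuracy, 0.95)
  expect_equal(nrow(res$results), 4)
  # ties prefer fewer hidden nodes, then lower learning rate
  top <- res$results[res$results$mean_accuracy == res$cv_accuracy, ]
  expect_equal(res$best$hidden, min(top$hidden))
  # a class smaller than the fold count shrinks folds with a warning
  small <- separable_features(n_per_class = 6, seed = 59)
  expect_warning(cross_validate(small$features, small$labels, folds = 10,
                                hyper_grid = grid[1, ], epochs = 30, seed = 59),
                 "reducing folds")
})

test_that("evaluation metrics follow the confusion-matrix identities", {
  # perfect predictions: identity-like confusion, all metrics 1, AUC 1
  d <- separable_features(n_per_class = 8, seed = 61)
  fit <- bpnn_train(d$features, d$labels, epochs = 600, seed = 61)
  rep <- evaluate(fit, d$features, d$labels)
  expect_equal(unname(diag(rep$confusion)), as.vector(table(d$labels)))
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$f1), rep(1, 3))
  expect_equal(unname(rep$auc), rep(1, 3))

  # micro-averaged recall equals accuracy for any confusion matrix
  set.seed(61)
  M <- matrix(rpois(9, 5), 3)
  r <- eval_report(M)
  micro_recall <- sum(diag(M)) / sum(M)
  expect_equal(r$accuracy, micro_recall)
  # F1 = precision = recall at the harmonic-mean fixed point
  sym <- matrix(c(5, 1, 1, 1, 5, 1, 1, 1, 5), 3)
  rs <- eval_report(sym)
  expect_equal(rs$f1, rs$precision)
  expect_equal(rs$precision, rs$recall)

  expect_error(evaluate(fit, d$features[0, ], integer(0)), "empty")
})

test_that("one-vs-rest AUC agrees with the pROC reference", {
  set.seed(67)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  ours <- pdglove:::auc_trapezoid(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
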