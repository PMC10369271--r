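TREMOR_CLASSES <- c("No tremor", "Mild tremor", "Severe tremor")

#' Train the 9-6-3 back-propagation network
#'
#' Fully connected network with nine inputs (the tremor feature vector), six
#' sigmoid hidden units and a three-way softmax output, trained by
#' mini-batch gradient descent on the cross-entropy loss.  Features are
#' standardised (per-feature mean/sd learned on the training set); a
#' constant feature gets sd 1 so standardisation stays finite.  Training is
#' deterministic given the seed: weight initialisation
#' (uniform +/- 1/sqrt(fan-in)) and batch shuffling both derive from it.
#'
#' @param features numeric matrix or data frame, `n x 9`.
#' @param labels integer vector in `{0, 1, 2}` (No / Mild / Severe tremor);
#'   all three classes must be present.
#' @param hidden number of hidden units (default 6).
#' @param lr learning rate (default 0.05).
#' @param epochs training epochs (default 500).
#' @param batch_size mini-batch size (default 16).
#' @param seed integer seed.
#' @return an object of class `bpnn`: weights `W1` (9 x hidden), `b1`,
#'   `W2` (hidden x 3), `b2`, the standardisation `scaler`, the per-epoch
#'   `loss` curve and the training configuration.
#' @export
bpnn_train <- function(features, labels, hidden = 6, lr = 0.05,
                       epochs = 500, batch_size = 16, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (ncol(X) != 9L) stop("expected 9 feature columns, got ", ncol(X))
  if (!all(is.finite(X))) stop("non-finite features")
  y <- as.integer(labels)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 training samples")
  if (!all(sort(unique(y)) %in% 0:2) || length(unique(y)) != 3L)
    stop("labels must cover all three classes {0, 1, 2}")

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Y <- matrix(0, n, 3L)
  Y[cbind(seq_len(n), y + 1L)] <- 1

  set.seed(seed)
  r1 <- 1 / sqrt(9); r2 <- 1 / sqrt(hidden)
  W1 <- matrix(stats::runif(9 * hidden, -r1, r1), 9, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(stats::runif(hidden * 3, -r2, r2), hidden, 3)
  b2 <- rep(0, 3)

  sigmoid <- function(z) 1 / (1 + exp(-z))
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- Xs[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      m <- length(idx)
      H <- sigmoid(sweep(Xb %*% W1, 2L, b1, "+"))
      Z <- sweep(H %*% W2, 2L, b2, "+")
      P <- softmax_rows(Z)
      dZ <- (P - Yb) / m                      # softmax + cross-entropy gradient
      dW2 <- t(H) %*% dZ
      dH <- dZ %*% t(W2) * H * (1 - H)        # sigmoid derivative
      dW1 <- t(Xb) %*% dH
      W2 <- W2 - lr * dW2; b2 <- b2 - lr * colSums(dZ)
      W1 <- W1 - lr * dW1; b1 <- b1 - lr * colSums(dH)
    }
    H <- sigmoid(sweep(Xs %*% W1, 2L, b1, "+"))
    P <- softmax_rows(sweep(H %*% W2, 2L, b2, "+"))
    loss_curve[ep] <- -mean(log(P[cbind(seq_len(n), y + 1L)] + 1e-15))
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 scaler = list(mean = mu, sd = sdv),
                 train_config = list(hidden = hidden, lr = lr,
                                     epochs = epochs, batch_size = batch_size,
                                     seed = seed),
                 loss = loss_curve),
            class = "bpnn")
}

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> 9-%d-3  final loss %.4f (%d epochs, lr %g, seed %d)\n",
              x$train_config$hidden, x$loss[length(x$loss)],
              x$train_config$epochs, x$train_config$lr, x$train_config$seed))
  invisible(x)
}

#' Predict tremor classes
#'
#' Forward pass through a trained network; the predicted class is the argmax
#' of the softmax outputs.  Probabilities are non-negative and sum to one
#' per sample.
#'
#' @param model a fitted `bpnn`.
#' @param features `n x 9` matrix of raw (unstandardised) features.
#' @return list with integer `labels` in `{0, 1, 2}` and an `n x 3`
#'   probability matrix `prob`.
#' @export
bpnn_predict <- function(model, features) {
  stopifnot(inherits(model, "bpnn"))
  X <- as.matrix(features)
  if (is.vector(features) && length(features) == 9L) X <- matrix(features, 1L)
  if (ncol(X) != 9L) stop("expected 9 feature columns, got ", ncol(X))
  Xs <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, "/")
  H <- 1 / (1 + exp(-sweep(Xs %*% model$W1, 2L, model$b1, "+")))
  P <- softmax_rows(sweep(H %*% model$W2, 2L, model$b2, "+"))
  colnames(P) <- TREMOR_CLASSES
  list(labels = max.col(P, ties.method = "first") - 1L, prob = P)
}

#' Stratified fold assignment
#'
#' Splits samples into `folds` groups whose sizes differ by at most one and
#' whose class proportions match the full data to within one sample per
#' class, by dealing the shuffled members of each class round-robin.
#'
#' @param labels class labels.
#' @param folds number of folds.
#' @param seed integer seed for the within-class shuffle.
#' @return integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(labels, folds = 10, seed = 1L) {
  y <- as.integer(labels)
  set.seed(seed)
  fold <- integer(length(y))
  offset <- 0L
  for (cls in sort(unique(y))) {
    members <- sample(which(y == cls))
    fold[members] <- ((seq_along(members) - 1L + offset) %% folds) + 1L
    offset <- offset + length(members)  # stagger so fold sizes balance
  }
  fold
}

#' Tenfold cross-validated hyperparameter search
#'
#' Evaluates every grid point by stratified k-fold cross-validation (each
#' sample tested exactly once per configuration) and returns the one with
#' the highest mean validation accuracy; ties go to fewer hidden nodes,
#' then lower learning rate.  A class with fewer members than `folds`
#' reduces the fold count with a warning.
#'
#' @param features `n x 9` feature matrix.
#' @param labels integer labels in `{0, 1, 2}`.
#' @param folds number of folds (default 10).
#' @param hyper_grid data frame with columns `hidden` and `lr` (default:
#'   hidden 4/6/8 crossed with lr 0.02/0.05).
#' @param epochs training epochs per fit (default 200 to keep the search
#'   affordable; the final model is refit with the full budget).
#' @param seed integer seed.
#' @return list with `best` (row of the grid), `cv_accuracy` (mean accuracy
#'   of the best point) and `results` (the grid with a `mean_accuracy`
#'   column).
#' @export
cross_validate <- function(features, labels, folds = 10, hyper_grid = NULL,
                           epochs = 200, seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (nrow(X) < folds) stop("fewer samples than folds")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning(sprintf("smallest class has %d members; reducing folds to %d",
                    min_class, min_class))
    folds <- min_class
  }
  if (is.null(hyper_grid))
    hyper_grid <- expand.grid(hidden = c(4, 6, 8), lr = c(0.02, 0.05))
  fold <- stratified_folds(y, folds, seed = seed)
  acc <- numeric(nrow(hyper_grid))
  for (g in seq_len(nrow(hyper_grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- bpnn_train(X[tr, , drop = FALSE], y[tr],
                        hidden = hyper_grid$hidden[g], lr = hyper_grid$lr[g],
                        epochs = epochs, seed = seed + f)
      pred <- bpnn_predict(fit, X[!tr, , drop = FALSE])$labels
      correct <- correct + sum(pred == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  results <- cbind(hyper_grid, mean_accuracy = acc)
  ord <- order(-acc, hyper_grid$hidden, hyper_grid$lr)
  best <- ord[1]
  list(best = hyper_grid[best, , drop = FALSE],
       cv_accuracy = acc[best], results = results)
}

#' Multiclass evaluation report from a confusion matrix
#'
#' Computes accuracy (trace over total) and per-class precision
#' (`conf[c,c] / colsum`, 0 when the column is empty), recall
#' (`conf[c,c] / rowsum`) and F1 (harmonic mean) from a 3x3 confusion
#' matrix with true classes in rows and predictions in columns.
#'
#' @param confusion 3x3 non-negative integer matrix, rows = true class
#'   (No / Mild / Severe), columns = predicted.
#' @param auc optional named per-class AUC vector to carry in the report.
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(confusion, auc = NULL) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == 3L, ncol(confusion) == 3L, all(confusion >= 0))
  dimnames(confusion) <- list(true = TREMOR_CLASSES, predicted = TREMOR_CLASSES)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  diagv <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  precision <- ifelse(colsum > 0, diagv / colsum, 0)
  recall <- ifelse(rowsum > 0, diagv / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = confusion,
                 accuracy = sum(diagv) / total,
                 precision = stats::setNames(precision, TREMOR_CLASSES),
                 recall = stats::setNames(recall, TREMOR_CLASSES),
                 f1 = stats::setNames(f1, TREMOR_CLASSES),
                 auc = auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% (n = %d)\n",
              100 * x$accuracy, sum(x$confusion)))
  tab <- data.frame(precision = sprintf("%.2f%%", 100 * x$precision),
                    recall = sprintf("%.2f%%", 100 * x$recall),
                    F1 = sprintf("%.2f%%", 100 * x$f1),
                    row.names = TREMOR_CLASSES)
  if (!is.null(x$auc)) tab$AUC <- sprintf("%.3f", x$auc)
  print(tab)
  invisible(x)
}

#' Evaluate a trained classifier on a test set
#'
#' Builds the confusion matrix from the model's predictions and computes the
#' full report, including one-vs-rest AUC per class by the trapezoidal rule
#' over the ranked class scores.
#'
#' @param model a fitted `bpnn`.
#' @param features `n x 9` test feature matrix.
#' @param labels integer test labels in `{0, 1, 2}`.
#' @return an `eval_report`.
#' @export
evaluate <- function(model, features, labels) {
  y <- as.integer(labels)
  if (length(y) == 0L) stop("empty test set")
  pred <- bpnn_predict(model, features)
  confusion <- matrix(0L, 3L, 3L)
  for (i in seq_along(y))
    confusion[y[i] + 1L, pred$labels[i] + 1L] <-
      confusion[y[i] + 1L, pred$labels[i] + 1L] + 1L
  auc <- vapply(1:3, function(c)
    auc_trapezoid(pred$prob[, c], as.integer(y == c - 1L)), numeric(1))
  eval_report(confusion, auc = stats::setNames(auc, TREMOR_CLASSES))
}

# One-vs-rest AUC by trapezoidal integration of the ROC curve traced by
# sweeping the score threshold; equals the rank statistic with tie correction.
auc_trapezoid <- function(scores, positive) {
  npos <- sum(positive == 1L); nneg <- sum(positive == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # cumulative counts at each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[keep]; fp <- cumsum(1 - p)[keep]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
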