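#' Supervised repertoire classification
#'
#' Call types are classified from two representations: the 8-feature
#' acoustic table (gradient-boosted trees after Shapley-value feature
#' screening, 70/30 train/test split) and the aligned mel-spectrograms (a
#' small convolutional network, 49/21/30 train/validation/test split). Both
#' are evaluated with accuracy, per-class precision, recall, f1 and the
#' confusion matrix on the held-out test split only.
#'
#' @name repertoire
NULL

#' Stratified train/validation/test split
#'
#' Splits indices into disjoint sets covering the data, per class when
#' `stratify = TRUE` (preserving class proportions within one call).
#'
#' @param labels class label vector.
#' @param fractions numeric vector of 2 (train/test) or 3
#'   (train/validation/test) positive fractions summing to 1.
#' @param stratify split within each class?
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `validation` (possibly
#'   empty), `test`.
#' @export
split_data <- function(labels, fractions = c(0.7, 0.3), stratify = TRUE,
                       seed = 1L) {
  if (!length(fractions) %in% 2:3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 2 or 3 positive values summing to 1")
  if (length(fractions) == 2L) fractions <- c(fractions[1], 0, fractions[2])
  set.seed(seed)
  n <- length(labels)
  groups <- if (stratify) split(seq_len(n), labels) else list(seq_len(n))
  tr <- va <- te <- integer(0)
  for (g in groups) {
    g <- sample(g)
    n_tr <- round(fractions[1] * length(g))
    n_va <- round(fractions[2] * length(g))
    n_tr <- min(n_tr, length(g))
    n_va <- min(n_va, length(g) - n_tr)
    tr <- c(tr, g[seq_len(n_tr)])
    if (n_va > 0) va <- c(va, g[n_tr + seq_len(n_va)])
    if (length(g) > n_tr + n_va) te <- c(te, g[(n_tr + n_va + 1):length(g)])
  }
  list(train = sort(tr), validation = sort(va), test = sort(te))
}

#' Classification report
#'
#' Confusion matrix plus the standard metrics: accuracy = correct/total,
#' per-class precision = TP/(TP+FP), recall = TP/(TP+FN), and
#' f1 = 2PR/(P+R) (0 when P+R = 0).
#'
#' @param pred predicted labels.
#' @param truth true labels, same length.
#' @param classes optional class ordering; default: sorted union.
#' @return `zr_report` list: `accuracy`, `per_class` (data.frame with
#'   precision/recall/f1/support), `confusion` (rows = truth,
#'   cols = predicted).
#' @export
evaluate <- function(pred, truth, classes = NULL) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length")
  if (is.null(classes)) classes <- sort(unique(c(as.character(pred),
                                                 as.character(truth))))
  pred <- factor(as.character(pred), levels = classes)
  truth <- factor(as.character(truth), levels = classes)
  cm <- table(truth = truth, predicted = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(tp) / length(truth),
    per_class = data.frame(class = classes, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           support = as.numeric(rowSums(cm))),
    confusion = cm), class = "zr_report")
}

#' @export
print.zr_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.3f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 3)
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# labels -> 0-based integer codes for xgboost
.xgb_codes <- function(labels, classes) match(as.character(labels), classes) - 1L

#' Screen features by Shapley-value importance
#'
#' Fits a gradient-boosted tree classifier on all candidate features and
#' computes the mean absolute Shapley additive attribution of each feature
#' (averaged over calls and classes); features whose mean |SHAP| exceeds
#' `threshold` are retained.
#'
#' @param X numeric feature matrix/data.frame (no missing values).
#' @param labels class labels (>= 2 classes).
#' @param threshold importance cutoff on mean |SHAP| (default 1, the
#'   screening rule used for the zebra repertoire).
#' @param nrounds,max_depth,eta parameters of the screening model.
#' @param seed integer seed.
#' @return list `selected` (feature names), `importance` (named, sorted
#'   mean |SHAP| per feature).
#' @export
select_features_by_importance <- function(X, labels, threshold = 1,
                                          nrounds = 60, max_depth = 4,
                                          eta = 0.3, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("candidate features must have no missing values")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least 2 classes")
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(X, label = .xgb_codes(labels, classes))
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  max_depth = max_depth, eta = eta, nthread = 1),
    data = dm, nrounds = nrounds, verbose = 0)
  # calls x classes x (features + bias); importance = mean over calls of
  # the per-feature |SHAP| summed over the class outputs
  contrib <- stats::predict(booster, dm, predcontrib = TRUE)
  imp <- apply(abs(contrib[, , colnames(X), drop = FALSE]), 3,
               function(m) mean(rowSums(m)))
  imp <- sort(imp, decreasing = TRUE)
  selected <- names(imp)[imp > threshold]
  if (length(selected) == 0)
    stop("no feature exceeds the importance threshold ", threshold,
         "; lower the threshold")
  list(selected = selected, importance = imp)
}

#' Train and evaluate the feature-based call-type classifier
#'
#' Gradient-boosted decision trees on the selected acoustic features:
#' the data are split 70/30 (stratified), hyperparameters (learning rate,
#' tree depth, tree count) are tuned by a small random search with 5-fold
#' cross-validation on the training split, the best model is refit on the
#' full training split and reported on the held-out test split only.
#'
#' @param X numeric feature matrix (selected features).
#' @param labels call-type labels.
#' @param fractions train/test fractions (default `c(0.7, 0.3)`).
#' @param n_trials random-search trials (default 20).
#' @param nfold cross-validation folds (default 5).
#' @param seed integer seed.
#' @return list: `model` (xgboost booster), `report` ([evaluate()] result on
#'   the test split), `best_params`, `split`, `classes`.
#' @export
train_feature_classifier <- function(X, labels, fractions = c(0.7, 0.3),
                                     n_trials = 20, nfold = 5, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least 2 classes")
  split <- split_data(labels, fractions, stratify = TRUE, seed = seed)
  if (length(unique(labels[split$train])) < length(classes))
    stop("a class is absent from the training split")
  ytr <- .xgb_codes(labels[split$train], classes)
  dtr <- xgboost::xgb.DMatrix(X[split$train, , drop = FALSE], label = ytr)
  set.seed(seed + 1L)
  grid <- data.frame(eta = stats::runif(n_trials, 0.05, 0.5),
                     max_depth = sample(2:8, n_trials, replace = TRUE),
                     nrounds = sample(30:150, n_trials, replace = TRUE))
  best <- NULL; best_err <- Inf
  for (i in seq_len(n_trials)) {
    cv <- xgboost::xgb.cv(
      params = list(objective = "multi:softprob",
                    num_class = length(classes), eta = grid$eta[i],
                    max_depth = grid$max_depth[i], nthread = 1),
      data = dtr, nrounds = grid$nrounds[i], nfold = nfold,
      metrics = "merror", verbose = 0)
    err <- min(cv$evaluation_log$test_merror_mean)
    if (err < best_err) { best_err <- err; best <- grid[i, ] }
  }
  model <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes), eta = best$eta,
                  max_depth = best$max_depth, nthread = 1),
    data = dtr, nrounds = best$nrounds, verbose = 0)
  prob <- stats::predict(model,
                         xgboost::xgb.DMatrix(X[split$test, , drop = FALSE]))
  pred <- classes[max.col(prob, ties.method = "first")]
  list(model = model, report = evaluate(pred, labels[split$test], classes),
       best_params = best, split = split, classes = classes)
}
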