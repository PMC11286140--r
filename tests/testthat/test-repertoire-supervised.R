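test_that("classification metrics match their definitions", {
  r <- evaluate(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$f1 == 1))

  # precision 0.5, recall 1.0 -> f1 = 2/3 for class a
  r2 <- evaluate(pred = c("a", "a", "b"), truth = c("a", "b", "b"))
  a <- r2$per_class[r2$per_class$class == "a", ]
  expect_equal(a$precision, 0.5)
  expect_equal(a$recall, 1)
  expect_equal(a$f1, 2 / 3)
  expect_error(evaluate(character(0), character(0)), "empty")
})

test_that("metrics equal a brute-force confusion oracle on random labels", {
  set.seed(21)
  classes <- c("qq", "sn", "ss", "sq")
  for (rep in 1:10) {
    truth <- sample(classes, 60, replace = TRUE)
    pred <- sample(classes, 60, replace = TRUE)
    r <- evaluate(pred, truth, classes)
    expect_equal(r$accuracy, sum(pred == truth) / 60)
    for (cl in classes) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(row$precision, prec)
      expect_equal(row$recall, rec)
      expect_equal(row$f1, f1)
      expect_equal(sum(r$confusion[cl, ]), sum(truth == cl))
    }
  }
})

test_that("splits are disjoint, cover the data and respect stratification", {
  labels <- rep(c("a", "b", "c", "d"), times = c(40, 30, 20, 10))
  s <- split_data(labels, c(0.49, 0.21, 0.30), seed = 3)
  all_idx <- c(s$train, s$validation, s$test)
  expect_equal(sort(all_idx), seq_along(labels))
  expect_equal(anyDuplicated(all_idx), 0)
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    expect_lte(abs(sum(labels[s$train] == cl) - 0.49 * n_cl), 1)
    expect_lte(abs(sum(labels[s$test] == cl) - 0.30 * n_cl), 1)
  }
  expect_error(split_data(labels, c(0.5, 0.2)), "sum")
})

test_that("importance screening finds the informative feature", {
  set.seed(22)
  n <- 240
  y <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
  X <- cbind(q50 = as.numeric(factor(y)) * 3 + rnorm(n, 0, 0.3),
             junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
  sel <- select_features_by_importance(X, y, threshold = 1)
  expect_equal(names(sel$importance)[1], "q50")
  expect_true("q50" %in% sel$selected)
  all_kept <- select_features_by_importance(X, y, threshold = 0)
  expect_setequal(all_kept$selected, colnames(X))
  expect_error(select_features_by_importance(X, y, threshold = 1e9),
               "threshold")
})

test_that("feature classifier learns separable types and rejects degenerate input", {
  d <- small_dataset()
  f <- d$features
  rf <- feature_names("repertoire")
  ok <- complete.cases(f[rf])
  fit <- train_feature_classifier(f[ok, rf], f$call_type[ok],
                                  n_trials = 4, seed = 2)
  expect_gte(fit$report$accuracy, 0.8)
  expect_error(train_feature_classifier(f[ok, rf],
                                        rep("snort", sum(ok))),
               "2 classes")
})

test_that("shuffled labels drive the classifier to chance", {
  d <- small_dataset()
  f <- d$features
  rf <- feature_names("repertoire")
  ok <- complete.cases(f[rf])
  set.seed(30)
  y <- sample(f$call_type[ok])
  fit <- train_feature_classifier(f[ok, rf], y, n_trials = 3, seed = 4)
  n_test <- length(fit$split$test)
  se <- sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(fit$report$accuracy - 0.25), 3 * se + 0.05)
})

cnn_toy <- function(n_per = 24, seed = 31) {
  # four coarse spectro-temporal patterns + noise, 16 x 20 frames
  set.seed(seed)
  p <- mel_params(44100); p$n_mels <- 16L; p$floor_db <- -80
  mk <- function(rows, cols) {
    m <- matrix(-80, 16, 20)
    m[rows, cols] <- -5 + rnorm(length(rows) * length(cols), 0, 3)
    attr(m, "mel_params") <- p
    class(m) <- "zr_melspec"
    m
  }
  specs <- c(replicate(n_per, mk(2:5, 1:20), simplify = FALSE),
             replicate(n_per, mk(10:14, 1:20), simplify = FALSE),
             replicate(n_per, mk(2:14, seq(1, 20, by = 4)), simplify = FALSE),
             replicate(n_per, mk(6:9, 10:20), simplify = FALSE))
  list(specs = specs, labels = rep(c("a", "b", "c", "d"), each = n_per))
}

test_that("the compact CNN separates distinct spectrogram patterns", {
  toy <- cnn_toy()
  cfg <- cnn_config(input_shape = c(16, 16), filters1 = 4, filters2 = 8,
                    dense = 16, epochs = 12, batch = 8)
  fit <- train_spectrogram_classifier(toy$specs, toy$labels,
                                      config = cfg, seed = 5)
  expect_gte(fit$report$accuracy, 0.8)
})

test_that("CNN training is deterministic for a fixed seed", {
  toy <- cnn_toy(n_per = 12)
  cfg <- cnn_config(input_shape = c(16, 16), filters1 = 4, filters2 = 8,
                    dense = 16, epochs = 4, batch = 8)
  f1 <- train_spectrogram_classifier(toy$specs, toy$labels,
                                     config = cfg, seed = 6)
  f2 <- train_spectrogram_classifier(toy$specs, toy$labels,
                                     config = cfg, seed = 6)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$report$confusion, f2$report$confusion)
})

test_that("constant spectrograms give chance-level CNN accuracy", {
  p <- mel_params(44100); p$n_mels <- 16L
  m <- matrix(-40, 16, 20)
  attr(m, "mel_params") <- p; class(m) <- "zr_melspec"
  specs <- replicate(48, m, simplify = FALSE)
  labels <- rep(c("a", "b", "c", "d"), each = 12)
  cfg <- cnn_config(input_shape = c(8, 8), filters1 = 2, filters2 = 4,
                    dense = 8, epochs = 3, batch = 8)
  fit <- train_spectrogram_classifier(specs, labels, config = cfg, seed = 7)
  expect_lte(fit$report$accuracy, 0.6)
  bad <- c(specs[-1], list(matrix(-40, 16, 21)))
  expect_error(train_spectrogram_classifier(bad, labels, config = cfg),
               "shape")
})
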