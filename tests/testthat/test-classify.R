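test_that("compute_metrics reproduces hand-computed values", {
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  m <- compute_metrics(y, y)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # confusion [[5,0,0],[0,0,5],[0,0,5]]: class 1 always predicted as 2
  y_true <- rep(0:2, each = 5)
  y_pred <- c(rep(0L, 5), rep(2L, 5), rep(2L, 5))
  expect_warning(m2 <- compute_metrics(y_true, y_pred), "never predicted")
  expect_equal(m2$recall, (1 + 0 + 1) / 3)
  expect_equal(m2$accuracy, 10 / 15)
  expect_equal(unname(m2$confusion["1", "2"]), 5)

  # degenerate: everything predicted as one class on balanced data
  expect_warning(m3 <- compute_metrics(rep(0:2, 10), rep(1L, 30),
                                       n_classes = 3))
  expect_equal(m3$accuracy, 1 / 3)
  expect_equal(m3$per_class$precision[c(1, 3)], c(0, 0))
  expect_true(is.finite(m3$f1))

  expect_error(compute_metrics(0:2, 0:1), "length mismatch")
})

test_that("metrics are invariant to sample order and trace-consistent", {
  set.seed(1)
  y_true <- sample(0:2, 60, replace = TRUE)
  y_pred <- sample(0:2, 60, replace = TRUE)
  perm <- sample(60)
  m1 <- suppressWarnings(compute_metrics(y_true, y_pred))
  m2 <- suppressWarnings(compute_metrics(y_true[perm], y_pred[perm]))
  expect_equal(m1[c("accuracy", "precision", "recall", "f1")],
               m2[c("accuracy", "precision", "recall", "f1")])
  expect_equal(m1$accuracy, sum(diag(m1$confusion)) / 60)
})

test_that("compiled KNN matches a pure-R reference", {
  set.seed(2)
  Xtr <- matrix(rnorm(60 * 5), 60)
  ytr <- sample(0:2, 60, replace = TRUE)
  Xte <- matrix(rnorm(25 * 5), 25)
  got <- neurofuse:::.knn_predict_cpp(Xtr, ytr, Xte,
                                      as.integer(0:4), 5L, 3L)
  ref <- knn_reference(Xtr, ytr, Xte, 5L, 3L)
  expect_equal(got, as.integer(ref))
})

test_that("every classifier is perfect on well-separated classes", {
  set.seed(3)
  n <- 60
  y <- rep(0:2, each = n / 3)
  X <- matrix(rnorm(n * 4, sd = 0.3), n) + 5 * cbind(y == 0, y == 1, y == 2, 0)
  for (clf in c("knn", "svm", "rf", "gb")) {
    rep <- kfold_evaluate(X, y, clf, k = 5, seed = 1)
    expect_equal(rep$mean[["accuracy"]], 1.0,
                 info = clf, tolerance = 1e-12)
  }
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 6), n)
  y <- rep(0:2, each = n / 3)
  # average over several permutations: CV folds correlate predictions, so a
  # single permutation wobbles beyond the iid binomial band
  accs <- vapply(1:5, function(i)
    kfold_evaluate(X, sample(y), "knn", k = 5,
                   seed = i)$mean[["accuracy"]], 0)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(mean(accs) - 1 / 3), se3)
})

test_that("kfold_evaluate supports k = 15, validates inputs, reproduces", {
  set.seed(5)
  n <- 90
  y <- rep(0:2, each = 30)
  X <- matrix(rnorm(n * 3), n) + 2 * cbind(y == 0, y == 1, y == 2)
  rep15 <- kfold_evaluate(X, y, "knn", k = 15, seed = 3)
  expect_equal(rep15$k_folds, 15L)
  expect_equal(nrow(rep15$per_fold), 15L)
  # confusion row sums equal class counts
  expect_equal(unname(rowSums(rep15$confusion)), as.vector(table(y)))

  expect_error(kfold_evaluate(X, y, "knn", k = 1), "k must be")
  expect_error(kfold_evaluate(X, rep(0L, n), "knn"), "single-class")
  expect_warning(kfold_evaluate(X[1:9, ], y[c(1:3, 31:33, 61:63)], "knn",
                                k = 5, seed = 1), "fewer members")

  r1 <- kfold_evaluate(X, y, "gb", k = 5, seed = 9)
  r2 <- kfold_evaluate(X, y, "gb", k = 5, seed = 9)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$confusion, r2$confusion)
})
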