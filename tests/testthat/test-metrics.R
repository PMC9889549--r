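test_that("confusion matrix counts match a per-sample loop", {
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  expect_equal(unname(confusion_matrix(y, y, 3)), diag(2L, 3),
               ignore_attr = TRUE)
  set.seed(500)
  labels <- sample(0:3, 40, replace = TRUE)
  pred <- sample(0:3, 40, replace = TRUE)
  cm <- confusion_matrix(labels, pred, 4)
  expect_equal(sum(cm), 40)
  manual <- matrix(0L, 4, 4)
  for (i in seq_along(labels)) {
    manual[labels[i] + 1, pred[i] + 1] <- manual[labels[i] + 1, pred[i] + 1] + 1L
  }
  expect_equal(unname(cm), manual)
  expect_error(confusion_matrix(0:2, 0:1, 3), "length")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 3), "lie in")
})

test_that("perfect and coin-flip confusions give their textbook metrics", {
  perfect <- diag(2L, 3)
  m <- multiclass_metrics(perfect)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  # 2x2 with every cell 1: per class TP=1 FN=1 FP=1 TN=1
  flat <- matrix(1L, 2, 2)
  m2 <- multiclass_metrics(flat)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
})

test_that("binary macro metrics reduce to the classical definitions", {
  set.seed(501)
  labels <- sample(0:1, 60, replace = TRUE)
  pred <- sample(0:1, 60, replace = TRUE)
  cm <- confusion_matrix(labels, pred, 2)
  m <- multiclass_metrics(cm)
  tp <- cm[2, 2]; fn <- cm[2, 1]; tn <- cm[1, 1]; fp <- cm[1, 2]
  sens1 <- tp / (tp + fn)      # recall of class 1
  spec1 <- tn / (tn + fp)
  # macro average of the two one-vs-rest recalls = (sens1 + spec1) / 2 and
  # macro specificity equals the same pair swapped
  expect_equal(m$sensitivity, mean(c(spec1, sens1)))
  expect_equal(m$specificity, mean(c(sens1, spec1)))
})

test_that("macro AUROC matches pROC and is 0.5 on label-independent scores", {
  set.seed(502)
  n <- 200
  labels <- sample(0:2, n, replace = TRUE)
  scores <- matrix(runif(n * 3), n, 3)
  scores[cbind(1:n, labels + 1)] <- scores[cbind(1:n, labels + 1)] +
    runif(n)
  scores <- scores / rowSums(scores)
  ours <- multiclass_metrics(confusion_matrix(labels, max.col(scores) - 1L, 3),
                             scores = scores, labels = labels)$auroc
  skip_if_not_installed("pROC")
  ref <- mean(sapply(0:2, function(k) {
    as.numeric(pROC::auc(pROC::roc(as.integer(labels == k), scores[, k + 1],
                                   quiet = TRUE, direction = "<")))
  }))
  expect_equal(ours, ref, tolerance = 1e-10)

  # independence: AUROC concentrates at 1/2
  set.seed(503)
  n <- 2000
  labels <- sample(0:1, n, replace = TRUE)
  scores <- matrix(runif(n * 2), n, 2)
  a <- multiclass_metrics(confusion_matrix(labels, max.col(scores) - 1L, 2),
                          scores = scores, labels = labels)$auroc
  expect_lt(abs(a - 0.5), 3 * 1 / sqrt(12 * n / 4))
})

test_that("an absent class is excluded from macro averages with a warning", {
  labels <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 1L, 1L, 1L)
  cm <- confusion_matrix(labels, pred, 3)
  expect_warning(m <- multiclass_metrics(cm), "absent")
  expect_equal(m$sensitivity, mean(c(1 / 2, 1)))
})

test_that("fold aggregation reports the arithmetic mean and population std", {
  same <- tibble::tibble(accuracy = c(0.8, 0.8), auroc = c(0.9, 0.9))
  rep1 <- aggregate_folds(same)
  expect_equal(unname(rep1$sd), c(0, 0))
  two <- tibble::tibble(fold = 1:2, accuracy = c(0.8, 1.0))
  rep2 <- aggregate_folds(two)
  expect_equal(unname(rep2$mean), 0.9)
  set.seed(504)
  x <- tibble::tibble(a = runif(5), b = runif(5))
  rep3 <- aggregate_folds(x)
  expect_lte(abs(rep3$mean[1] - sum(x$a) / 5), 1e-12)
  expect_lte(abs(rep3$sd[2] - sqrt(sum((x$b - mean(x$b))^2) / 5)), 1e-12)
})

test_that("accuracy equals the mean per-sample correctness", {
  set.seed(505)
  for (r in 1:5) {
    labels <- sample(0:2, 30, replace = TRUE)
    pred <- sample(0:2, 30, replace = TRUE)
    m <- multiclass_metrics(confusion_matrix(labels, pred, 3))
    expect_equal(m$accuracy, mean(labels == pred))
  }
})
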