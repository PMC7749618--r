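test_that("pooled t from summaries matches t.test on raw data", {
  set.seed(3)
  x <- rnorm(20, 5, 2); y <- rnorm(30, 4, 2)
  ours <- pooled_t(mean(x), sd(x), 20, mean(y), sd(y), 30)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  ref_w <- t.test(x, y)
  ours_w <- pooled_t(mean(x), sd(x), 20, mean(y), sd(y), 30,
                     var_equal = FALSE)
  expect_equal(ours_w$statistic, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-9)
})

test_that("pooled t is zero under equality, antisymmetric, flagged when
           degenerate", {
  expect_equal(pooled_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  a <- pooled_t(7.5, 0.2, 40, 7.9, 0.25, 60)
  b <- pooled_t(7.9, 0.25, 60, 7.5, 0.2, 40)
  expect_equal(a$statistic, -b$statistic)
  deg <- pooled_t(1, 0, 5, 2, 0, 5)
  expect_true(is.infinite(deg$statistic))
  expect_true(attr(deg$statistic, "flagged"))
})

test_that("pooled t reproduces the published occipital iAPF statistics from
           the printed group summaries", {
  o1 <- pooled_t(7.5723, 0.24, 46, 7.9223, 0.21, 63)
  o2 <- pooled_t(7.5120, 0.23, 46, 7.9059, 0.23, 63)
  expect_equal(o1$statistic, -8.138, tolerance = 0.01)
  expect_equal(o2$statistic, -8.812, tolerance = 0.01)
  expect_lt(o1$p.value, 1e-4)
  expect_lt(o2$p.value, 1e-4)
})

test_that("AUC is the pair-counting statistic with half-credit ties", {
  sep <- roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  ex <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))
  expect_equal(ex$auc, 2 / 3)   # 2 of 3 positive-negative pairs win
  expect_error(roc_auc(1:4, rep(1, 4)), "two classes")
})

test_that("ROC polyline is monotone from (0,0) to (1,1) and its trapezoid
           area equals the rank AUC", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    scores <- if (i %% 3 == 0) sample(1:4, n, TRUE) else rnorm(n)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    ra <- roc_auc(scores, labels)
    rp <- ra$roc_points
    expect_equal(rp[1, ], c(FPR = 0, TPR = 0))
    expect_equal(rp[nrow(rp), ], c(FPR = 1, TPR = 1))
    expect_true(all(diff(rp[, 1]) >= 0) && all(diff(rp[, 2]) >= 0))
    expect_lt(abs(alphassa:::trapezoid_auc(rp) - ra$auc), 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- c(rnorm(30), rnorm(30, 1))
  labels <- rep(c(0, 1), each = 30)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validated linear SVM is perfect on separated classes and
           chance-level on permuted labels", {
  set.seed(1)
  X <- data.frame(f1 = c(rnorm(50), rnorm(50, 10)),
                  f2 = rnorm(100))
  y <- rep(c("a", "b"), each = 50)
  cv <- crossval_linear_svm(X, y, k = 10, seed = 0)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$auc, 1)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))

  yp <- sample(y)   # permutation null
  cvp <- crossval_linear_svm(X, yp, k = 10, seed = 0)
  expect_gte(cvp$mean_accuracy, 0.35)
  expect_lte(cvp$mean_accuracy, 0.65)
})

test_that("cross-validation is deterministic and scale-invariant", {
  set.seed(2)
  X <- data.frame(a = c(rnorm(30), rnorm(30, 1.5)), b = rnorm(60))
  y <- rep(c("g1", "g2"), each = 30)
  cv1 <- crossval_linear_svm(X, y, seed = 7)
  cv2 <- crossval_linear_svm(X, y, seed = 7)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_identical(cv1$pooled_scores, cv2$pooled_scores)

  X2 <- X; X2$a <- 1000 * X2$a + 5   # affine rescale of one column
  cv3 <- crossval_linear_svm(X2, y, seed = 7)
  expect_equal(cv3$fold_accuracies, cv1$fold_accuracies)
  expect_equal(cv3$auc, cv1$auc, tolerance = 1e-8)

  expect_error(crossval_linear_svm(X, y, feature_subset = "zz"), "unknown")
})
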