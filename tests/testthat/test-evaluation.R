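test_that("confusion matrices tally exhaustively and reject bad input", {
  perfect <- confusion_matrix(
    c("HIGH", "LOW", "NOT_SUITABLE"),
    c("HIGH", "LOW", "NOT_SUITABLE")
  )
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))
  single <- confusion_matrix("HIGH", "LOW")
  expect_identical(single$counts["HIGH", "LOW"], 1L)
  expect_identical(sum(single$counts), 1L)
  expect_error(confusion_matrix(c("HIGH"), c("HIGH", "LOW")),
    class = "cropsense_validation_error"
  )
  expect_error(confusion_matrix("HIGH", "MAYBE"),
    class = "cropsense_validation_error"
  )
})

test_that("1000 random label pairs match an independent tally", {
  set.seed(10)
  truth <- sample(land_classes(), 1000, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  pred <- sample(land_classes(), 1000, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  expect_identical(cm$counts, brute_force_confusion(truth, pred))
  expect_equal(accuracy(cm), mean(truth == pred))
})

test_that("precision, recall and F1 follow their formulas with the zero convention", {
  cm <- confusion_matrix(
    c("HIGH", "HIGH", "LOW", "NOT_SUITABLE"),
    c("HIGH", "LOW", "LOW", "HIGH")
  )
  m <- precision_recall_f1(cm, "HIGH")
  expect_equal(m[["precision"]], 1 / 2) # TP 1, FP 1
  expect_equal(m[["recall"]], 1 / 2) # TP 1, FN 1
  expect_equal(m[["f1"]], 1 / 2)
  # a class never predicted and never true -> all zeros, with warnings
  cm2 <- confusion_matrix(c("HIGH", "LOW"), c("HIGH", "LOW"))
  # both the precision and the recall denominators are zero here
  expect_warning(
    expect_warning(m2 <- precision_recall_f1(cm2, "NOT_SUITABLE"), "undefined"),
    "undefined"
  )
  expect_equal(unname(m2), c(0, 0, 0))
})

test_that("F1 extremes and harmonic-mean bounds hold", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.5), 0)
  set.seed(11)
  for (i in 1:500) {
    p <- runif(1, 0.01, 1)
    r <- runif(1, 0.01, 1)
    f1 <- f1_score(p, r)
    expect_lte(f1, max(p, r) + 1e-12)
    expect_gte(f1, min(p, r) - 1e-12)
  }
})

test_that("accuracy covers the perfect, worst and random cases", {
  perfect <- confusion_matrix(rep("HIGH", 4), rep("HIGH", 4))
  expect_equal(accuracy(perfect), 1)
  worst <- confusion_matrix(
    c("HIGH", "HIGH", "LOW", "LOW"),
    c("LOW", "LOW", "HIGH", "HIGH")
  )
  expect_equal(accuracy(worst), 0)
  set.seed(12)
  truth <- sample(land_classes(), 300, replace = TRUE)
  pred <- sample(land_classes(), 300, replace = TRUE)
  expect_equal(accuracy(confusion_matrix(truth, pred)), mean(truth == pred))
})

test_that("the classification report reproduces the class-by-metric layout", {
  set.seed(13)
  truth <- sample(land_classes(), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(land_classes(), 200, replace = TRUE))
  report <- classification_report(confusion_matrix(truth, pred))
  expect_identical(report$class, land_classes())
  expect_true(all(c("precision", "recall", "f1", "support") %in% names(report)))
  expect_identical(sum(report$support), 200L)
  expect_equal(
    report$f1,
    purrr::map2_dbl(report$precision, report$recall, f1_score)
  )
})

test_that("regression errors follow the printed formulas", {
  same <- regression_errors(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mae, 0)
  expect_equal(same$rmse, 0)
  hand <- regression_errors(c(1, 2, 3), c(2, 2, 2))
  expect_equal(hand$mae, 2 / 3)
  expect_equal(hand$rmse, sqrt(2 / 3))
  const <- regression_errors(rnorm(10), rnorm(10) + 0) # placeholder lengths
  expect_identical(const$n, 10L)
  shifted <- regression_errors(1:5, 1:5 + 2.5)
  expect_equal(shifted$mae, 2.5)
  expect_equal(shifted$rmse, 2.5)
  expect_error(regression_errors(1:3, 1:4), class = "cropsense_validation_error")
})

test_that("RMSE dominates MAE on random inputs and both match brute force", {
  set.seed(14)
  for (i in 1:300) {
    n <- sample(2:50, 1)
    a <- rnorm(n, sd = runif(1, 0.1, 10))
    b <- rnorm(n, sd = runif(1, 0.1, 10))
    e <- regression_errors(a, b)
    expect_gte(e$rmse, e$mae - 1e-12)
    expect_equal(e$mae, sum(abs(a - b)) / n)
    expect_equal(e$rmse, sqrt(sum((a - b)^2) / n))
  }
})

test_that("percent improvement reproduces the baseline arithmetic", {
  expect_equal(percent_improvement(1.41, 0.19), 86.5)
  expect_equal(percent_improvement(0.95, 0.19), 80.0)
  expect_equal(percent_improvement(2, 2), 0)
  expect_equal(percent_improvement(1, 1.5), -50)
  expect_error(percent_improvement(0, 0.1), class = "cropsense_validation_error")
})
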