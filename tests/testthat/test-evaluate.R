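test_that("confusion counts partition the input with apnea positive", {
  cm <- confusionCounts(c("A", "A", "N"), c("A", "N", "N"))
  expect_identical(c(cm@TP, cm@FP, cm@TN, cm@FN), c(1L, 0L, 1L, 1L))

  # degenerate all-N predictor: TP = FP = 0
  cm0 <- confusionCounts(c("A", "N", "A"), rep("N", 3))
  expect_identical(c(cm0@TP, cm0@FP), c(0L, 0L))

  # random cases against a direct enumeration oracle
  set.seed(14)
  for (i in 1:5) {
    labels <- sample(c("N", "A"), 20, replace = TRUE)
    pred <- sample(c("N", "A"), 20, replace = TRUE)
    cm <- confusionCounts(labels, pred)
    expect_identical(cm@TP, sum(labels == "A" & pred == "A"))
    expect_identical(cm@FP, sum(labels == "N" & pred == "A"))
    expect_identical(cm@TN, sum(labels == "N" & pred == "N"))
    expect_identical(cm@FN, sum(labels == "A" & pred == "N"))
    expect_identical(cm@TP + cm@FP + cm@TN + cm@FN, 20L)
    # permutation invariance
    perm <- sample(20)
    expect_identical(confusionCounts(labels[perm], pred[perm]), cm)
  }

  expect_error(confusionCounts(c("A", "N"), "A"), "length mismatch")
  expect_error(confusionCounts(c("A", "X"), c("A", "N")), "X")
})

test_that("percent metrics reproduce the published confusion matrices", {
  # validation/withheld counts
  val <- classificationMetrics(confusionMatrix(TP = 5287, FP = 854,
                                               TN = 9863, FN = 1230))
  expect_equal(unname(val), c(87.9, 81.1, 92.0))
  # training/released counts
  tr <- classificationMetrics(confusionMatrix(TP = 6092, FP = 562,
                                              TN = 9760, FN = 565))
  expect_equal(unname(tr), c(93.4, 91.5, 94.6))
  # perfect two-segment case
  expect_equal(unname(classificationMetrics(
    confusionMatrix(1, 0, 1, 0))), c(100, 100, 100))
})

test_that("zero-denominator metrics are flagged, not silently zero", {
  cm <- confusionMatrix(TP = 0, FP = 0, TN = 5, FN = 0)  # no positives
  expect_warning(m <- classificationMetrics(cm), "sensitivity")
  expect_true(is.nan(m[["sensitivity"]]))
  expect_identical(attr(m, "undefined"), "sensitivity")
  expect_equal(m[["specificity"]], 100)
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(15)
  for (i in 1:20) {
    counts <- rmultinom(1, 200, runif(4, 0.05, 1))
    cm <- confusionMatrix(counts[1], counts[2], counts[3], counts[4])
    m <- classificationMetrics(cm, digits = NA)
    nPos <- cm@TP + cm@FN
    nNeg <- cm@TN + cm@FP
    expected <- (nPos * m[["sensitivity"]] + nNeg * m[["specificity"]]) /
      (nPos + nNeg)
    expect_equal(m[["accuracy"]], unname(expected), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  # perfectly separated scores
  expect_equal(rocAuc(c(.9, .8, .3, .2), c("A", "A", "N", "N"))$auc, 1)
  # fixed 6-point case with a tie
  s6 <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  l6 <- c("A", "N", "A", "N", "A", "N")
  expect_equal(rocAuc(s6, l6)$auc, pairwiseAuc(s6, l6))
  # random small cases, with and without ties
  set.seed(16)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    labels <- c("A", "N", sample(c("N", "A"), n - 2, replace = TRUE))
    scores <- if (i %% 2) runif(n) else
      sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(rocAuc(scores, labels)$auc, pairwiseAuc(scores, labels),
                 label = sprintf("case %d", i))
  }
  # uninformative scores at n = 2000 sit near 0.5
  set.seed(17)
  labels <- sample(c("N", "A"), 2000, replace = TRUE)
  expect_equal(rocAuc(runif(2000), labels)$auc, 0.5, tolerance = 0.05)

  expect_error(rocAuc(runif(5), rep("A", 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (i in 1:5) {
    labels <- c("A", "N", sample(c("N", "A"), 48, replace = TRUE))
    scores <- runif(50) + 0.5 * (labels == "A")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("N", "A"),
      direction = "<", quiet = TRUE)))
    expect_equal(rocAuc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid monotone staircase", {
  set.seed(19)
  labels <- sample(c("N", "A"), 300, replace = TRUE)
  scores <- runif(300) + 0.3 * (labels == "A")
  roc <- rocAuc(scores, labels)$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})
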