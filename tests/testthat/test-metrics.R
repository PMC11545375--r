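test_that("confusion counts match direct element counting", {
  cm <- confusion(c(1, 0), c(1, 0))
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cm2 <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(cm2$tp, cm2$tn, cm2$fp, cm2$fn), c(0L, 0L, 2L, 2L))

  set.seed(3)
  yt <- rbinom(50, 1, 0.5)
  yp <- rbinom(50, 1, 0.5)
  cm3 <- confusion(yt, yp)
  brute <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in 1:50) {
    k <- if (yt[i] == 1 && yp[i] == 1) "tp" else
      if (yt[i] == 0 && yp[i] == 0) "tn" else
        if (yt[i] == 0 && yp[i] == 1) "fp" else "fn"
    brute[k] <- brute[k] + 1L
  }
  expect_equal(c(cm3$tp, cm3$tn, cm3$fp, cm3$fn), unname(brute))
  expect_equal(cm3$tp + cm3$tn + cm3$fp + cm3$fn, 50L)

  expect_error(confusion(c(1, 0), c(1)), class = "metric_error")
  expect_error(confusion(c(1, 2), c(1, 0)), class = "metric_error")
})

test_that("the headline test-split confusion reproduces all five metrics", {
  # TP=44 TN=48 FP=2 FN=6 on a balanced 100-instance evaluation set
  m <- classification_metrics(confusion_counts(44, 48, 2, 6), 100, 100)
  expect_equal(m$accuracy, 0.92)
  expect_equal(round(m$jaccard, 2), 0.85)
  expect_equal(m$jaccard, 92 / 108)
  expect_equal(round(m$f1, 2), 0.92)
  expect_equal(m$f1, 88 / 96)
  expect_equal(m$sensitivity, 0.88)
  expect_equal(m$specificity, 0.96)
})

test_that("80 correct of 100 gives the 0.67 Jaccard variant", {
  m <- classification_metrics(confusion_counts(40, 40, 10, 10), 100, 100)
  expect_equal(m$jaccard, 80 / 120)
  expect_equal(round(m$jaccard, 2), 0.67)
})

test_that("perfect classification yields all-ones metrics", {
  m <- classification_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(unlist(unclass(m)), c(accuracy = 1, jaccard = 1, f1 = 1,
                                     sensitivity = 1, specificity = 1))
})

test_that("metrics stay in [0,1] and jaccard = acc/(2-acc) when A = P = N", {
  set.seed(8)
  for (k in 1:50) {
    cnt <- as.integer(rmultinom(1, 60, c(0.3, 0.3, 0.2, 0.2))) + 1L
    m <- classification_metrics(confusion_counts(cnt[1], cnt[2], cnt[3],
                                                 cnt[4]))
    vals <- unlist(unclass(m))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(m$jaccard, m$accuracy / (2 - m$accuracy))
  }
})

test_that("degenerate denominators raise instead of silently returning 0", {
  expect_error(classification_metrics(confusion_counts(5, 0, 0, 5)),
               class = "degenerate_metric_error") # no negatives
  expect_error(classification_metrics(confusion_counts(0, 5, 5, 0)),
               class = "degenerate_metric_error") # no positives
})

test_that("feature decreasing rate matches the reference subset sizes", {
  expect_equal(round(feature_decreasing_rate(16, 473), 2), 0.97)
  expect_equal(round(feature_decreasing_rate(29, 473), 2), 0.94)
  expect_equal(round(feature_decreasing_rate(205, 473), 2), 0.57)
  expect_equal(feature_decreasing_rate(0, 473), 1)
  expect_equal(feature_decreasing_rate(473, 473), 0)
  expect_error(feature_decreasing_rate(474, 473), class = "metric_error")
})

test_that("fitness is the documented affine combination", {
  expect_equal(fitness_score(1, 1), 1)
  expect_equal(fitness_score(0, 0), 0)
  # the 221-feature individual with training accuracy 0.70
  expect_equal(fitness_score(0.70, 1 - 221 / 473),
               0.9 * 0.70 + 0.1 * (252 / 473))
  # monotone in each argument
  expect_gt(fitness_score(0.8, 0.5), fitness_score(0.7, 0.5))
  expect_gt(fitness_score(0.8, 0.6), fitness_score(0.8, 0.5))
  expect_error(fitness_score(1.2, 0), class = "metric_error")
  expect_error(fitness_weights(0.8, 0.1), class = "config_error")
})

test_that("metric rows serialize in benchmark-table column order", {
  m <- classification_metrics(confusion_counts(44, 48, 2, 6))
  row <- metric_row(m, 16, 473, "proposed")
  expect_equal(names(row), c("Method", "NSF", "FDR", "Accuracy", "JC", "F1",
                             "Sens.", "Spec."))
  expect_equal(row$NSF, 16L)
  expect_equal(round(row$FDR, 2), 0.97)
})
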